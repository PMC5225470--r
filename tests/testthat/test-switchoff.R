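test_that("contact classes are orbits under the chain rotation", {
  fx <- mediumTetramerFixture()
  cs <- enumerateContactClasses(fx$net)
  cls <- cs@classes
  # intra-subunit class: one member per chain, same residue pair
  intra <- cls[cls$kind == "intra-subunit" & cls$nMembers == 4L, ][1L, ]
  mem <- cs@members[cs@members$classId == intra$classId, ]
  s <- fx$s
  expect_setequal(s@chain[mem$i], c("A", "B", "C", "D"))
  expect_true(all(s@chain[mem$i] == s@chain[mem$j]))
  expect_setequal(unique(paste(s@resno[mem$i], s@resno[mem$j])),
                  paste(intra$resI, intra$resJ))
  # inter-subunit class between adjacent chains: the A-B, B-C, C-D, D-A ring
  inter <- cls[cls$kind == "inter-subunit" & cls$nMembers == 4L, ]
  if (nrow(inter)) {
    mem <- cs@members[cs@members$classId == inter$classId[1L], ]
    pairs <- sort(paste0(s@chain[mem$i], s@chain[mem$j]))
    expect_length(unique(s@chain[c(mem$i, mem$j)]), 4L)
    expect_length(pairs, 4L)
  }
  # classes partition the noncovalent contacts
  ct <- contacts(fx$net)
  expect_identical(nrow(cs@members), sum(ct$kind == "noncovalent"))
})

test_that("a ring of single contacts between adjacent chains forms the expected orbits", {
  # two residues per chain; only res1-res1 and res2-res2 touch across
  # adjacent chains: 8 noncovalent contacts in exactly 2 orbits
  xyzA <- rbind(c(6, 0, 0), c(6, 0, 9))
  xyz <- rbind(xyzA,
               cbind(-xyzA[, 2L], xyzA[, 1L], xyzA[, 3L]),
               cbind(-xyzA[, 1L], -xyzA[, 2L], xyzA[, 3L]),
               cbind(xyzA[, 2L], -xyzA[, 1L], xyzA[, 3L]))
  s <- CaStructure(chain = rep(c("A", "B", "C", "D"), each = 2L),
                   resno = rep(1:2, 4L), resname = "GLY", xyz = xyz)
  net <- buildContactMap(s)
  ct <- contacts(net)
  expect_identical(sum(ct$kind == "noncovalent"), 8L)
  cs <- enumerateContactClasses(net)
  expect_identical(nrow(cs@classes), 2L)
  expect_true(all(cs@classes$nMembers == 4L))
  expect_true(all(cs@classes$kind == "inter-subunit"))
})

test_that("switch-off is an involution: removing then restoring gives the baseline", {
  fx <- mediumTetramerFixture()
  cs <- enumerateContactClasses(fx$net)
  mem <- cs@members[cs@members$classId == cs@classes$classId[5L], ]
  rows <- match(paste(mem$i, mem$j),
                paste(contacts(fx$net)$i, contacts(fx$net)$j))
  net2 <- fx$net
  net2@contacts <- rbind(fx$net@contacts[-rows, ], fx$net@contacts[rows, ])
  net2@contacts <- net2@contacts[order(net2@contacts$i, net2@contacts$j), ]
  rownames(net2@contacts) <- NULL
  expect_identical(net2@contacts, fx$net@contacts)
})

test_that("fast-path and full-rebuild switch-off responses agree", {
  fx <- mediumTetramerFixture()
  cs <- enumerateContactClasses(fx$net)
  set.seed(3)
  some <- sample(cs@classes$classId, 5L)
  for (cid in some) {
    mem <- cs@members[cs@members$classId == cid, ]
    fast <- switchOffResponse(fx$net, mem, fx$force, covariance = fx$cov,
                              method = "woodbury")
    full <- switchOffResponse(fx$net, mem, fx$force, method = "rebuild")
    expect_false(fast$disconnecting || full$disconnecting)
    expect_lt(max(abs(fast$response@deltaR - full$response@deltaR)) /
                max(abs(full$response@deltaR)), 1e-8)
  }
})

test_that("covalent springs are not eligible for switch-off", {
  fx <- mediumTetramerFixture()
  ct <- contacts(fx$net)
  cov1 <- ct[ct$kind == "covalent", ][1L, ]
  expect_error(switchOffResponse(fx$net, data.frame(i = cov1$i, j = cov1$j),
                                 fx$force), "covalent")
})

test_that("a removal that leaves a node under-constrained is flagged, not scored", {
  # chain A: rigid 5-node pyramid; chain B: one node pinned by exactly
  # three springs -- removing one leaves a mechanism (rank deficiency)
  s <- CaStructure(chain = c(rep("A", 5L), "B"), resno = c(1:5, 1L),
                   resname = "GLY",
                   xyz = rbind(c(0, 0, 0), c(5, 0, 0), c(0, 5, 0), c(5, 5, 0),
                               c(2.5, 2.5, 4), c(2.5, -3.5, 4)))
  net <- buildContactMap(s, cutoff = 8)
  ct <- contacts(net)
  expect_identical(sum(ct$i == 6L | ct$j == 6L), 3L)
  cov <- pseudoInverse(networkSpectrum(net))  # baseline is rigid
  dang <- ct[ct$i == 1L & ct$j == 6L, ]
  expect_identical(dang$kind, "noncovalent")
  f <- new("ForceVector", f = c(rep(0, 15L), 1, 0, 0), beta = 1,
           description = "probe")
  for (m in c("woodbury", "rebuild")) {
    res <- switchOffResponse(net, dang, f, method = m, covariance = cov)
    expect_true(res$disconnecting)
    expect_null(res$response)
  }
})

test_that("zero force or an infinite threshold yields no significant contacts", {
  fx <- keystoneTetramer()
  zero <- new("ForceVector", f = numeric(3L * nNodes(fx$s)), beta = 1,
              description = "zero")
  sc0 <- screenContacts(fx$net, zero, deltaThreshold = 0.1, minResidues = 1L)
  expect_false(any(sc0$significant))
  f <- bindingPocketForce(fx$s, fx$pocket)
  scInf <- screenContacts(fx$net, f, deltaThreshold = Inf, minResidues = 1L)
  expect_false(any(scInf$significant))
})

test_that("significance is monotone in both thresholds", {
  fx <- keystoneTetramer()
  f <- bindingPocketForce(fx$s, fx$pocket)
  cs <- enumerateContactClasses(fx$net)
  cov <- pseudoInverse(networkSpectrum(fx$net))
  key <- function(sc) paste(sc$chainI, sc$resI, sc$chainJ, sc$resJ)[sc$significant]
  loose <- screenContacts(fx$net, f, deltaThreshold = 0.05, minResidues = 3L,
                          classSet = cs, covariance = cov)
  tightD <- screenContacts(fx$net, f, deltaThreshold = 0.2, minResidues = 3L,
                           classSet = cs, covariance = cov)
  tightR <- screenContacts(fx$net, f, deltaThreshold = 0.05, minResidues = 8L,
                           classSet = cs, covariance = cov)
  expect_true(all(key(tightD) %in% key(loose)))
  expect_true(all(key(tightR) %in% key(loose)))
})

test_that("the engineered keystone class ranks first and counts match across subunits", {
  fx <- keystoneTetramer()
  f <- bindingPocketForce(fx$s, fx$pocket)
  sc <- screenContacts(fx$net, f, deltaThreshold = 0.1, minResidues = 5L)
  top <- sc[1L, ]
  expect_identical(top$kind, "inter-subunit")
  expect_setequal(c(top$resI, top$resJ), c(fx$tipRes, fx$recRes))
  expect_true(top$significant)
  expect_gt(top$minCount, sc$minCount[2L])  # strictly dominant
  # exact C4 symmetry: per-subunit counts agree for every scored class
  scored <- sc[!sc$disconnecting, ]
  expect_true(all(scored$A == scored$B & scored$B == scored$C &
                    scored$C == scored$D))
})
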