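# tiny 12-node tetramer (3 residues/chain) for handcrafted mode patterns
tinyTetramer <- function() {
  xyzA <- rbind(c(6, 0, 0), c(6, 0, 3.8), c(6, 3, 5))
  xyz <- rbind(xyzA,
               cbind(-xyzA[, 2L], xyzA[, 1L], xyzA[, 3L]),
               cbind(-xyzA[, 1L], -xyzA[, 2L], xyzA[, 3L]),
               cbind(xyzA[, 2L], -xyzA[, 1L], xyzA[, 3L]))
  CaStructure(chain = rep(c("A", "B", "C", "D"), each = 3L),
              resno = rep(1:3, 4L), resname = "GLY", xyz = xyz)
}

# wrap handcrafted per-residue magnitude patterns (rows of `mags`) into a
# fake spectrum whose "modes" have those magnitudes
spectrumFromMagnitudes <- function(mags) {
  V <- do.call(cbind, lapply(seq_len(nrow(mags)), function(k)
    as.vector(rbind(mags[k, ], 0, 0))))
  new("NetworkSpectrum", values = seq_len(ncol(V)), vectors = V,
      nullCount = 0L, fingerprint = "handcrafted")
}

test_that("quarter correlation separates fourfold-repeating from localized patterns", {
  s <- tinyTetramer()
  repeating <- rep(c(1, 2, 3), 4L)          # identical in all four chains
  localized <- c(5, 1, 4, rep(0, 9L))       # confined to chain A
  sp <- spectrumFromMagnitudes(rbind(repeating, localized))
  cl <- suppressMessages(classifyDegeneracy(sp, s))
  expect_true(cl$nondegenerate[1L])
  expect_equal(cl$minQuarterCor[1L], 1)
  expect_false(cl$nondegenerate[2L])        # flat quarters: r forced to 0
  expect_equal(cl$minQuarterCor[2L], 0)
  expect_message(classifyDegeneracy(sp, s), "zero-variance")
})

test_that("the degeneracy threshold is strict: r exactly at 0.95 is degenerate", {
  q1 <- c(1, 2, 3)
  c1 <- q1 - mean(q1)
  perp <- c(1, -2, 1); perp <- perp / sqrt(sum(perp^2)) * sqrt(sum(c1^2))
  q2 <- mean(q1) + 0.95 * c1 + sqrt(1 - 0.95^2) * perp  # cor(q1, q2) = 0.95
  expect_equal(cor(q1, q2), 0.95, tolerance = 1e-12)
  s <- tinyTetramer()
  atBoundary <- c(q1, q2, q1, q1)
  sp <- spectrumFromMagnitudes(rbind(atBoundary))
  r <- classifyDegeneracy(sp, s, threshold = 0)$minQuarterCor[1L]
  expect_equal(r, 0.95, tolerance = 1e-9)
  # threshold equal to the observed minimum: strict > makes it degenerate
  expect_false(classifyDegeneracy(sp, s, threshold = r)$nondegenerate[1L])
  expect_true(classifyDegeneracy(sp, s, threshold = r - 1e-9)$nondegenerate[1L])
})

test_that("classification requires equal chains", {
  s <- CaStructure(chain = c("A", "A", "B", "C", "D"), resno = c(1:2, 1L, 1L, 1L),
                   resname = "GLY", xyz = matrix(rnorm(15), 5L))
  sp <- new("NetworkSpectrum", values = 1, vectors = matrix(rnorm(15), 15L, 1L),
            nullCount = 0L, fingerprint = "x")
  expect_error(classifyDegeneracy(sp, s), "tetramer")
})

test_that("overlap is the absolute cosine", {
  expect_equal(modeOverlap(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(modeOverlap(c(1, 0), c(0, 1)), 0)
  expect_equal(modeOverlap(c(1, 0), c(1, 1)), sqrt(2) / 2)
  expect_equal(modeOverlap(c(1, 0), c(-1, 0)), 1)  # sign-blind
  expect_error(modeOverlap(c(0, 0), c(1, 0)), "zero")
})

test_that("known combinations of non-degenerate modes are recovered exactly", {
  fx <- mediumTetramerFixture()
  cl <- classifyDegeneracy(fx$sp, fx$s)
  nd <- cl$mode[cl$nondegenerate]
  V <- eigenVectors(fx$sp)[, nullCount(fx$sp) + nd, drop = FALSE]
  # single mode
  one <- bestLinearCombination(fx$sp, cl, V[, 1L], k = 1L)
  expect_identical(one@modes, nd[1L])
  expect_equal(abs(one@coefficients), 1, tolerance = 1e-10)
  expect_equal(one@overlap, 1, tolerance = 1e-10)
  # equal two-mode mixture
  d2 <- (V[, 1L] + V[, 2L]) / sqrt(2)
  two <- bestLinearCombination(fx$sp, cl, d2, k = 2L)
  expect_setequal(two@modes, nd[1:2])
  expect_equal(abs(two@coefficients), rep(sqrt(2) / 2, 2L), tolerance = 1e-10)
  expect_equal(two@overlap, 1, tolerance = 1e-10)
  # random 5-mode combination is recovered to machine precision
  set.seed(21)
  coef <- rnorm(5L)
  d5 <- drop(V[, 1:5] %*% coef)
  five <- bestLinearCombination(fx$sp, cl, d5, k = 5L)
  expect_setequal(five@modes, nd[1:5])
  expect_equal(five@overlap, 1, tolerance = 1e-10)
})

test_that("requesting more modes than are non-degenerate is an error", {
  fx <- mediumTetramerFixture()
  cl <- classifyDegeneracy(fx$sp, fx$s)
  expect_error(bestLinearCombination(fx$sp, cl, fx$response@deltaR,
                                     k = sum(cl$nondegenerate) + 1L),
               "non-degenerate")
})

test_that("flipping an eigenvector's sign changes no overlap or classification", {
  fx <- mediumTetramerFixture()
  cl <- classifyDegeneracy(fx$sp, fx$s)
  spFlip <- fx$sp
  flip <- nullCount(fx$sp) + cl$mode[cl$nondegenerate][1L]
  spFlip@vectors[, flip] <- -spFlip@vectors[, flip]
  clFlip <- classifyDegeneracy(spFlip, fx$s)
  expect_identical(cl$nondegenerate, clFlip$nondegenerate)
  d <- fx$response@deltaR
  a <- bestLinearCombination(fx$sp, cl, d, k = 3L)
  b <- bestLinearCombination(spFlip, clFlip, d, k = 3L)
  expect_identical(a@modes, b@modes)
  expect_equal(abs(a@coefficients), abs(b@coefficients), tolerance = 1e-12)
  expect_equal(a@overlap, b@overlap, tolerance = 1e-12)
})

test_that("cumulative overlap is non-decreasing and reaches 1 on generated targets", {
  fx <- mediumTetramerFixture()
  cl <- classifyDegeneracy(fx$sp, fx$s)
  nd <- cl$mode[cl$nondegenerate]
  V <- eigenVectors(fx$sp)[, nullCount(fx$sp) + nd, drop = FALSE]
  set.seed(8)
  d <- drop(V[, 1:6] %*% rnorm(6L))
  rep6 <- cumulativeOverlapReport(fx$sp, cl, d, kMax = 10L)
  expect_true(all(diff(rep6$overlap) >= -1e-12))
  expect_equal(rep6$overlap[6L], 1, tolerance = 1e-10)
  # LRT target: still monotone
  repLRT <- cumulativeOverlapReport(fx$sp, cl, fx$response@deltaR, kMax = 8L)
  expect_true(all(diff(repLRT$overlap) >= -1e-12))
  expect_true(all(repLRT$overlap >= 0 & repLRT$overlap <= 1 + 1e-12))
})

test_that("C4 symmetry pairs degenerate eigenvalues; isolated modes are symmetric", {
  fx <- mediumTetramerFixture()
  cl <- classifyDegeneracy(fx$sp, fx$s)
  lam <- cl$eigenvalue
  relGap <- pmin(c(Inf, diff(lam)), c(diff(lam), Inf)) / lam
  paired <- relGap < 1e-6
  # two-fold (E-representation) modes come in eigenvalue pairs; every mode
  # the quarter-correlation rule calls degenerate belongs to such a pair
  expect_true(all(paired[!cl$nondegenerate]))
  # symmetry-isolated modes repeat exactly across the four subunits
  expect_true(all(cl$nondegenerate[!paired]))
  expect_gt(min(cl$minQuarterCor[!paired]), 0.999)
})

test_that("greedy top-k selection equals exhaustive best-subset for orthonormal modes", {
  fx <- mediumTetramerFixture()
  cl <- classifyDegeneracy(fx$sp, fx$s)
  nd <- cl$mode[cl$nondegenerate][1:8]      # restrict to 8 candidates
  clSub <- cl
  clSub$nondegenerate <- cl$mode %in% nd
  d <- fx$response@deltaR
  V <- eigenVectors(fx$sp)[, nullCount(fx$sp) + nd, drop = FALSE]
  dhat <- d / sqrt(sum(d * d))
  a <- drop(crossprod(V, dhat))
  for (k in c(2L, 3L)) {
    greedy <- bestLinearCombination(fx$sp, clSub, d, k = k)
    best <- 0
    for (sub in utils::combn(8L, k, simplify = FALSE))
      best <- max(best, sqrt(sum(a[sub]^2)))
    expect_equal(greedy@overlap, best, tolerance = 1e-10)
  }
})
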