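# Shared fixtures, built in code and memoized for the duration of a run.

.fixtureCache <- new.env(parent = emptyenv())

getFixture <- function(name, builder) {
  if (!exists(name, envir = .fixtureCache)) {
    assign(name, builder(), envir = .fixtureCache)
  }
  get(name, envir = .fixtureCache)
}

# default-conditions tetramer (120 residues/chain) with its ANM machinery
defaultTetramerFixture <- function() {
  getFixture("tetramer480", function() {
    s <- generateC4Tetramer(seed = 1)
    net <- buildContactMap(s)
    sp <- networkSpectrum(net)
    cov <- pseudoInverse(sp)
    force <- bindingPocketForce(s, c(40L, 42L, 46L, 58L, 67L, 108L))
    list(s = s, net = net, sp = sp, cov = cov, force = force,
         response = lrtResponse(cov, force))
  })
}

# smaller tetramer for the switch-off acceptance work (50 residues/chain)
mediumTetramerFixture <- function() {
  getFixture("tetramer200", function() {
    s <- generateC4Tetramer(nResiduesPerChain = 50L, seed = 7,
                            pocketResidues = c(10L, 12L, 20L, 25L, 33L, 44L))
    net <- buildContactMap(s)
    sp <- networkSpectrum(net)
    cov <- pseudoInverse(sp)
    force <- bindingPocketForce(s, c(10L, 12L, 20L, 25L, 33L, 44L))
    list(s = s, net = net, sp = sp, cov = cov, force = force,
         response = lrtResponse(cov, force))
  })
}

withSeedHelper <- function(seed, expr) {
  set.seed(seed)
  expr
}

# single-chain random connected toy: jittered 3D grid, spacing 5 A
randomConnectedToy <- function(n, seed = 1) {
  set.seed(seed)
  g <- as.matrix(expand.grid(x = 0:2, y = 0:2, z = 0:2)) * 5
  g <- g[seq_len(n), , drop = FALSE] + matrix(runif(3 * n, -0.5, 0.5), n, 3L)
  CaStructure(chain = rep("A", n), resno = seq_len(n), resname = "ALA", xyz = g)
}

# finite-difference Hessian of the ANM potential (independent oracle)
fdHessian <- function(network, step = 1e-4) {
  x0 <- coords(network@structure)
  n3 <- 3L * nrow(x0)
  evalV <- function(v) networkEnergy(network, x0 + matrix(v, ncol = 3L, byrow = TRUE))
  H <- matrix(0, n3, n3)
  for (a in seq_len(n3)) for (b in a:n3) {
    ea <- numeric(n3); eb <- numeric(n3)
    ea[a] <- step; eb[b] <- step
    H[a, b] <- (evalV(ea + eb) - evalV(ea - eb) - evalV(eb - ea) + evalV(-ea - eb)) /
      (4 * step^2)
    H[b, a] <- H[a, b]
  }
  H
}

# independent minimal NMD reader (parses only what the writer's format spec
# defines: a coordinates line and a mode line)
readNMDVector <- function(path) {
  lines <- readLines(path)
  modeLine <- lines[startsWith(lines, "mode ")][1L]
  parts <- strsplit(modeLine, " +")[[1L]]
  as.numeric(parts[-(1:3)])  # drop "mode", index, scale
}

readNMDCoords <- function(path) {
  lines <- readLines(path)
  cl <- lines[startsWith(lines, "coordinates ")][1L]
  as.numeric(strsplit(cl, " +")[[1L]][-1L])
}

# Engineered keystone tetramer. Each chain: a dense 7-residue cluster
# near the axis (res 1-7; the four clusters form a connected ring), a
# second 7-residue cluster above and further out (res 8-14) resting on
# its own lower cluster through a narrow hinge patch, a tip residue 15
# protruding towards the next chain and a receiver residue 16 protruding
# towards the previous one. The ONLY noncovalent contact joining
# adjacent upper units is tip(X)-receiver(next chain): one
# inter-subunit class at a long lever arm. Removing it leaves each upper
# unit held only by its short-lever hinge, so the response to a force on
# the upper unit changes drastically -- the class must rank first in the
# switch-off screen. Pocket residues (8, 10, 15) load the upper units.
keystoneTetramer <- function() {
  getFixture("keystone", function() {
    off <- rbind(c(0, 0, -2.2), c(2.2, 0, 0), c(0, 2.2, 0),
                 c(-1.6, -1.6, 0), c(0, 0, 2.2),
                 c(-2.2, 0, 0), c(0, -2.2, 0)) * 1.4
    lower <- sweep(off, 2L, c(8, 0, 2.2), `+`)
    upper <- sweep(off, 2L, c(14, 0, 9.5), `+`)
    tip <- c(14, 8, 9.5)
    rec <- c(14, -8, 9.5)
    xyzA <- rbind(lower, upper, tip, rec)
    xyz <- rbind(xyzA,
                 cbind(-xyzA[, 2L], xyzA[, 1L], xyzA[, 3L]),
                 cbind(-xyzA[, 1L], -xyzA[, 2L], xyzA[, 3L]),
                 cbind(xyzA[, 2L], -xyzA[, 1L], xyzA[, 3L]))
    n <- nrow(xyzA)
    s <- CaStructure(chain = rep(c("A", "B", "C", "D"), each = n),
                     resno = rep(seq_len(n), 4L),
                     resname = "ALA", xyz = xyz)
    net <- buildContactMap(s)
    list(s = s, net = net, tipRes = 15L, recRes = 16L,
         pocket = c(8L, 10L, 15L))
  })
}
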