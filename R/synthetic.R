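## Synthetic C4-symmetric toy tetramers.
##
## Chain A is a compact bundle of short alpha-helical columns placed on a
## serpentine grid, joined by adaptive arc loops so that every
## consecutive-Calpha distance stays in [3.0, 4.5] Angstrom. Seeded
## Gaussian jitter is applied BEFORE symmetrization, then chains B, C, D
## are exact 90/180/270 degree rotations of A about the z axis (rotation
## matrices with exact 0/+-1 entries), so the C4 symmetry of the output
## is exact to machine precision -- which the mode-degeneracy analysis
## relies on.

rotZ90 <- function(xyz, k) {
  # k quarter turns about z, exact entries
  for (q in seq_len(k %% 4L)) xyz <- cbind(-xyz[, 2L], xyz[, 1L], xyz[, 3L])
  xyz
}

# k intermediate points between anchors p and q with consecutive spacing
# in [3.0, 4.5] A: straight interpolation when the chord allows it,
# otherwise a circular arc bulging along `bulge` whose span is solved so
# the chord per step is ~3.8 A.
loopPoints <- function(p, q, k, bulge = c(0, 0, 1)) {
  D <- sqrt(sum((q - p)^2))
  nseg <- k + 1L
  if (D / nseg > 4.45)
    stop("loop anchors too far apart for ", k, " residues", call. = FALSE)
  if (D / nseg >= 3.05) {
    t <- seq_len(k) / nseg
    return(t(vapply(t, function(tt) p + tt * (q - p), numeric(3L))))
  }
  e1 <- (q - p) / D
  b <- bulge - sum(bulge * e1) * e1
  nb <- sqrt(sum(b * b))
  if (nb < 1e-8) { b <- c(1, 0, 0) - e1[1L] * e1; nb <- sqrt(sum(b * b)) }
  e2 <- b / nb
  target <- 3.8
  spacing <- function(phi) D * sin(phi / (2 * nseg)) / sin(phi / 2)
  phi <- stats::uniroot(function(ph) spacing(ph) - target,
                        lower = 1e-6, upper = 2 * pi - 1e-3)$root
  R <- D / (2 * sin(phi / 2))
  m <- (p + q) / 2
  ctr <- m - R * cos(phi / 2) * e2
  theta <- -phi / 2 + seq_len(k) / nseg * phi
  t(vapply(theta, function(th) ctr + R * (sin(th) * e1 + cos(th) * e2),
           numeric(3L)))
}

buildChainTrace <- function(n, helixSegments, colSpacing = 8,
                            helixRadius = 2.3, rise = 1.5, turn = 100 * pi / 180) {
  seg <- helixSegments
  nSeg <- nrow(seg)
  grid <- cbind(c(0, 1, 2, 2, 1, 0), c(0, 0, 0, 1, 1, 1)) * colSpacing
  if (nSeg > nrow(grid)) {
    extra <- nSeg - nrow(grid)
    grid <- rbind(grid, cbind(rev(seq_len(extra)) - 1, 2) * colSpacing)
  }
  grid <- sweep(grid[seq_len(nSeg), , drop = FALSE], 2,
                colMeans(grid[seq_len(nSeg), , drop = FALSE]))
  xyz <- matrix(NA_real_, n, 3L)
  zCur <- 0
  for (s in seq_len(nSeg)) {
    L <- seg$end[s] - seg$start[s] + 1L
    up <- (s %% 2L) == 1L
    j <- seq_len(L) - 1L
    ang <- (s - 1L) * 0.7 + j * turn
    z <- zCur + (if (up) j else -j) * seg$pitch[s]
    xyz[seg$start[s]:seg$end[s], ] <-
      cbind(grid[s, 1L] + helixRadius * cos(ang),
            grid[s, 2L] + helixRadius * sin(ang), z)
    zCur <- z[L]
  }
  zMid <- mean(range(xyz[, 3L], na.rm = TRUE))
  # loops between consecutive helices
  for (s in seq_len(nSeg - 1L)) {
    a <- seg$end[s]; b <- seg$start[s + 1L]
    k <- b - a - 1L
    if (k > 0L) {
      up <- xyz[a, 3L] > zMid
      xyz[(a + 1L):(b - 1L), ] <-
        loopPoints(xyz[a, ], xyz[b, ], k, bulge = c(0, 0, if (up) 1 else -1))
    } else {
      d <- sqrt(sum((xyz[a, ] - xyz[b, ])^2))
      if (d < 3.0 || d > 4.5)
        stop("adjacent helix segments leave no loop residue but are ",
             round(d, 2), " A apart", call. = FALSE)
    }
  }
  # leading / trailing coil residues extend away from the bundle
  extendCoil <- function(idxs, anchor, prev) {
    dir <- anchor - prev
    dir <- dir / sqrt(sum(dir * dir))
    t(vapply(seq_along(idxs), function(k) anchor + 3.6 * k * dir, numeric(3L)))
  }
  first <- seg$start[1L]; last <- seg$end[nSeg]
  if (first > 1L)
    xyz[(first - 1L):1L, ] <- extendCoil(seq_len(first - 1L),
                                         xyz[first, ], xyz[first + 1L, ])
  if (last < n)
    xyz[(last + 1L):n, ] <- extendCoil(seq_len(n - last),
                                       xyz[last, ], xyz[last - 1L, ])
  xyz
}

defaultHelixSegments <- function(n) {
  # six helices of 18 residues with 2-residue loops for the default 120;
  # scaled proportionally for other lengths
  nSeg <- max(2L, min(6L, n %/% 20L))
  per <- n %/% nSeg
  L <- per - 2L
  starts <- 1L + (seq_len(nSeg) - 1L) * per
  data.frame(start = starts, end = starts + L - 1L, pitch = 1.5)
}

.neutralCycle <- c("ALA", "GLY", "LEU", "SER", "VAL", "THR", "ILE", "PRO",
                   "PHE", "TYR", "TRP", "MET", "ASN", "GLN", "CYS", "HIS")

#' Generate an exactly C4-symmetric toy tetramer
#'
#' Builds one chain as a bundle of short helical columns (consecutive
#' Calpha spacing ~3.8 A) with small seeded Gaussian jitter applied
#' before symmetrization, then replicates it by exact 90/180/270 degree
#' rotations about the z axis into chains A-D. The result has the
#' geometric properties the downstream analysis assumes: exact C4
#' symmetry, equal-length chains, and a 10 A contact graph that is a
#' single connected body (verified; the subunit radius is tightened by
#' 10\% up to 5 times if not, then an error is raised).
#'
#' @param nResiduesPerChain residues per chain (>= 20; default 120).
#' @param radius distance of the subunit centroid from the C4 (z) axis
#'   in Angstrom.
#' @param helixSegments data.frame(start, end, pitch) of helical segments
#'   within one chain; default: six 18-residue helices with 2-residue
#'   loops (for 120 residues).
#' @param pocketResidues per-chain residue numbers designated as the
#'   ligand-binding pocket (default six residues: 40, 42, 46, 58, 67, 108).
#' @param chargeSpec named integer vector mapping residue number to
#'   formal charge; charged residues are renamed ARG (+) / GLU (-).
#' @param seed integer seed; same seed gives bit-identical coordinates.
#' @param jitterSd standard deviation (A) of the pre-symmetrization
#'   coordinate jitter.
#' @param cutoff contact cutoff (A) used for the connectivity check.
#' @return a [CaStructure-class] with chains A, B, C, D.
#' @examples
#' s <- generateC4Tetramer(nResiduesPerChain = 40, seed = 1)
#' isC4Tetramer(s)
#' @export
generateC4Tetramer <- function(nResiduesPerChain = 120L,
                               radius = 20,
                               helixSegments = NULL,
                               pocketResidues = c(40L, 42L, 46L, 58L, 67L, 108L),
                               chargeSpec = NULL,
                               seed = 1L,
                               jitterSd = 0.05,
                               cutoff = 10) {
  n <- as.integer(nResiduesPerChain)
  if (n < 20L) stop("nResiduesPerChain must be >= 20", call. = FALSE)
  if (radius <= 0) stop("radius must be positive", call. = FALSE)
  if (missing(pocketResidues) && n < max(pocketResidues)) {
    # canonical pocket assumes the default chain length; scale for shorter chains
    pocketResidues <- unique(as.integer(round(seq(0.3 * n, 0.9 * n,
                                                  length.out = 6L))))
  }
  if (any(pocketResidues < 1L | pocketResidues > n))
    stop("pocket residues outside chain range", call. = FALSE)
  if (is.null(helixSegments)) helixSegments <- defaultHelixSegments(n)
  stopifnot(all(c("start", "end", "pitch") %in% names(helixSegments)))

  resname <- rep_len(.neutralCycle, n)
  charge <- integer(n)
  if (!is.null(chargeSpec)) {
    at <- as.integer(names(chargeSpec))
    if (any(at < 1L | at > n)) stop("chargeSpec residue outside chain", call. = FALSE)
    charge[at] <- as.integer(chargeSpec)
    resname[at][chargeSpec > 0] <- "ARG"
    resname[at][chargeSpec < 0] <- "GLU"
  }

  base <- buildChainTrace(n, helixSegments)
  for (attempt in 0:4) {
    r <- radius * 0.9^attempt
    xyzA <- withSeed(seed + attempt, {
      jit <- matrix(stats::rnorm(3L * n, sd = jitterSd), n, 3L)
      sweep(base + jit, 2, c(r, 0, 0), `+`)
    })
    xyz <- rbind(xyzA, rotZ90(xyzA, 1L), rotZ90(xyzA, 2L), rotZ90(xyzA, 3L))
    s <- CaStructure(chain = rep(c("A", "B", "C", "D"), each = n),
                     resno = rep(seq_len(n), 4L),
                     resname = rep(resname, 4L), xyz = xyz,
                     charge = rep(charge, 4L))
    if (isConnectedAtCutoff(s, cutoff)) return(s)
  }
  stop("could not generate a connected tetramer at cutoff ", cutoff,
       " A (5 attempts with shrinking radius)", call. = FALSE)
}

# run expr with a temporary RNG state
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

isConnectedAtCutoff <- function(structure, cutoff) {
  net <- buildContactMap(structure, cutoff = cutoff)
  ct <- contacts(net)
  n <- nNodes(structure)
  if (nrow(ct) == 0L) return(n == 1L)
  comp <- seq_len(n)                       # union-find with path halving
  find <- function(a) { while (comp[a] != a) { comp[a] <<- comp[comp[a]]; a <- comp[a] }; a }
  for (k in seq_len(nrow(ct))) {
    ra <- find(ct$i[k]); rb <- find(ct$j[k])
    if (ra != rb) comp[ra] <- rb
  }
  length(unique(vapply(seq_len(n), find, integer(1L)))) == 1L
}

#' Pseudo-ligand centroid of a binding pocket
#'
#' Arithmetic mean of the pocket Calpha coordinates, displaced 2 A toward
#' the C4 (z) axis so the point is interior to the subunit and never
#' coincides with a pocket Calpha. Stands in for the geometric center of
#' a bound ligand's heavy atoms, which does not exist at Calpha
#' resolution; only the force direction derived from it matters.
#'
#' @param x a [CaStructure-class].
#' @param chain chain identifier.
#' @param pocketResidues residue numbers of the pocket (>= 1).
#' @return length-3 numeric coordinate.
#' @export
pocketCentroid <- function(x, chain, pocketResidues) {
  if (length(pocketResidues) < 1L) stop("empty pocket", call. = FALSE)
  idx <- nodeIndex(x, chain, pocketResidues)
  ctr <- colMeans(coords(x)[idx, , drop = FALSE])
  rad <- sqrt(ctr[1L]^2 + ctr[2L]^2)
  if (rad <= 2)
    stop("pocket centroid within 2 A of the C4 axis; cannot displace inward",
         call. = FALSE)
  ctr - 2 * c(ctr[1L], ctr[2L], 0) / rad
}
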