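## Mode classification and overlap decomposition.
##
## Non-null modes are numbered 1..3N-6 by ascending eigenvalue (global
## index). A mode is non-degenerate when its per-residue magnitude
## pattern repeats in all four subunits: the N-vector of magnitudes is
## split into four chain-quarters and all six pairwise Pearson
## correlations must exceed the threshold (strictly).

# column-wise Pearson correlation between two matrices of equal shape;
# zero-variance columns give r = 0 (flagged by the caller)
colPearson <- function(A, B) {
  n <- nrow(A)
  mA <- colMeans(A); mB <- colMeans(B)
  cov <- colSums(A * B) / n - mA * mB
  vA <- colSums(A * A) / n - mA^2
  vB <- colSums(B * B) / n - mB^2
  bad <- vA <= 0 | vB <= 0
  r <- ifelse(bad, 0, cov / sqrt(pmax(vA, 0) * pmax(vB, 0)))
  list(r = r, degenerateVariance = bad)
}

#' Classify modes as degenerate vs non-degenerate by C4 symmetry
#'
#' For every non-null mode, the per-residue displacement magnitudes are
#' computed and split into four chain-quarters; the mode is
#' non-degenerate iff all six pairwise Pearson correlations between
#' quarters are strictly greater than the threshold. A quarter with zero
#' variance makes its pairs count as r = 0 (degenerate) and is reported
#' via a message.
#'
#' @param spectrum a [NetworkSpectrum-class] of the tetramer's network.
#' @param structure the matching [CaStructure-class] tetramer (4 equal
#'   chains; unequal chains are an error).
#' @param threshold correlation threshold (default 0.95; strict >).
#' @return data.frame(mode, eigenvalue, minQuarterCor, nondegenerate)
#'   with one row per non-null mode, global indices ascending.
#' @export
classifyDegeneracy <- function(spectrum, structure, threshold = 0.95) {
  stopifnot(is(spectrum, "NetworkSpectrum"), is(structure, "CaStructure"))
  assertTetramer(structure, "mode classification")
  n <- nNodes(structure)
  nper <- n %/% 4L
  keep <- (spectrum@nullCount + 1L):length(spectrum@values)
  V <- spectrum@vectors[, keep, drop = FALSE]
  # per-residue magnitudes of every mode: N x nModes
  M <- sqrt(V[seq(1L, 3L * n, 3L), , drop = FALSE]^2 +
            V[seq(2L, 3L * n, 3L), , drop = FALSE]^2 +
            V[seq(3L, 3L * n, 3L), , drop = FALSE]^2)
  quarters <- lapply(0:3, function(q)
    M[(q * nper + 1L):((q + 1L) * nper), , drop = FALSE])
  minR <- rep(Inf, ncol(M))
  anyZeroVar <- FALSE
  for (a in 1:3) for (b in (a + 1L):4L) {
    cp <- colPearson(quarters[[a]], quarters[[b]])
    minR <- pmin(minR, cp$r)
    anyZeroVar <- anyZeroVar || any(cp$degenerateVariance)
  }
  if (anyZeroVar)
    message("zero-variance quarter(s) encountered; affected correlations set to 0")
  data.frame(mode = seq_along(keep),
             eigenvalue = spectrum@values[keep],
             minQuarterCor = minR,
             nondegenerate = minR > threshold)
}

#' Overlap (absolute cosine) between two vectors
#'
#' I = |v . d| / (||v|| ||d||), in [0, 1]: 1 means the mode fully
#' describes the displacement, 0 that they are orthogonal. The absolute
#' value is taken because eigenvector sign is arbitrary.
#'
#' @param v,d nonzero numeric vectors of equal length.
#' @return scalar in [0, 1].
#' @export
modeOverlap <- function(v, d) {
  stopifnot(length(v) == length(d))
  nv <- sqrt(sum(v * v)); nd <- sqrt(sum(d * d))
  if (nv == 0 || nd == 0) stop("overlap undefined for a zero vector", call. = FALSE)
  abs(sum(v * d)) / (nv * nd)
}

# overlaps of all non-degenerate modes with target d, plus bookkeeping
nondegenOverlaps <- function(spectrum, classification, d) {
  cand <- classification$mode[classification$nondegenerate]
  if (!length(cand)) stop("no non-degenerate modes", call. = FALSE)
  keepCols <- spectrum@nullCount + cand
  V <- spectrum@vectors[, keepCols, drop = FALSE]
  dhat <- d / sqrt(sum(d * d))
  a <- drop(crossprod(V, dhat))        # projections of normalized target
  list(cand = cand, V = V, a = a, dhat = dhat)
}

#' Best linear combination of k non-degenerate modes
#'
#' Ranks the non-degenerate modes by individual overlap with the target
#' (descending), takes the top k, and combines them with coefficients
#' a_i = v_i . d_hat (the projections of the normalized target onto the
#' orthonormal modes). Because the modes are orthonormal, this top-k
#' selection is also the best subset of size k.
#'
#' @param spectrum a [NetworkSpectrum-class].
#' @param classification output of [classifyDegeneracy()].
#' @param d target 3N vector (e.g. the LRT displacement).
#' @param k number of modes to combine (>= 1).
#' @return a [ModeCombination-class]; \code{modes} are global indices.
#' @export
bestLinearCombination <- function(spectrum, classification, d, k) {
  stopifnot(k >= 1L)
  ov <- nondegenOverlaps(spectrum, classification, d)
  if (length(ov$cand) < k)
    stop(sprintf("only %d non-degenerate modes available, need %d",
                 length(ov$cand), k), call. = FALSE)
  ord <- order(-abs(ov$a), ov$cand)    # ties: lowest global index first
  sel <- ord[seq_len(k)]
  comb <- drop(ov$V[, sel, drop = FALSE] %*% ov$a[sel])
  new("ModeCombination",
      modes = as.integer(ov$cand[sel]),
      coefficients = ov$a[sel],
      combined = comb,
      overlap = modeOverlap(comb, d))
}

setMethod("show", "ModeCombination", function(object) {
  cat(sprintf("ModeCombination: modes [%s], overlap %.4f\n",
              paste(object@modes, collapse = ", "), object@overlap))
  invisible(object)
})

#' Cumulative overlap of mode combinations
#'
#' For k = 1..kMax, the overlap of the best k-mode combination with the
#' target, with the chosen global mode indices. The overlap column is
#' non-decreasing in k (nested orthonormal projections).
#'
#' @param spectrum a [NetworkSpectrum-class].
#' @param classification output of [classifyDegeneracy()].
#' @param d target 3N vector.
#' @param kMax largest combination size (capped at the number of
#'   non-degenerate modes).
#' @return data.frame(k, modes, overlap); \code{modes} is a
#'   comma-separated list of global indices.
#' @export
cumulativeOverlapReport <- function(spectrum, classification, d, kMax) {
  ov <- nondegenOverlaps(spectrum, classification, d)
  kMax <- min(kMax, length(ov$cand))
  ord <- order(-abs(ov$a), ov$cand)
  res <- lapply(seq_len(kMax), function(k) {
    sel <- ord[seq_len(k)]
    data.frame(k = k,
               modes = paste(ov$cand[sel], collapse = ","),
               overlap = sqrt(sum(ov$a[sel]^2)))
  })
  do.call(rbind, res)
}
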