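## Anisotropic network model: contact map, Hessian, spectrum, covariance.
##
## Potential: V = 1/2 sum_contacts gamma_ij (r_ij - r_ij^0)^2, summed over
## residue pairs closer than the cutoff (plus backbone-consecutive pairs).
## The Hessian at equilibrium has off-diagonal 3x3 blocks
## H_ij = -(gamma_ij / r^2) d d^T with d the equilibrium separation
## vector, and diagonal blocks H_ii = -sum_j H_ij.

GAMMA_COVALENT <- 82      # RT/A^2, backbone-consecutive pairs
GAMMA_NONCOVALENT <- 3.166  # RT/A^2, Miyazawa-Jernigan average

#' Build the ANM contact network of a structure
#'
#' A pair (i, j) is a contact iff its Euclidean distance is strictly
#' smaller than the cutoff, or i and j are consecutive residues of the
#' same chain (backbone, "covalent", kept regardless of distance).
#' Covalent springs get gamma = 82 RT/A^2, all other contacts
#' 3.166 RT/A^2 (the Miyazawa-Jernigan average for noncovalent
#' interactions). Cross-chain pairs are never covalent.
#'
#' @param structure a [CaStructure-class] with at least 2 residues.
#' @param cutoff contact cutoff in Angstrom (default 10).
#' @param gammaCovalent,gammaNoncovalent spring constants in RT/A^2.
#' @return an [ElasticNetwork-class].
#' @examples
#' s <- generateC4Tetramer(nResiduesPerChain = 30, seed = 1)
#' net <- buildContactMap(s)
#' table(contacts(net)$kind)
#' @export
buildContactMap <- function(structure, cutoff = 10,
                            gammaCovalent = GAMMA_COVALENT,
                            gammaNoncovalent = GAMMA_NONCOVALENT) {
  stopifnot(is(structure, "CaStructure"))
  n <- nNodes(structure)
  if (n < 2L) stop("need at least 2 residues", call. = FALSE)
  D <- as.matrix(stats::dist(coords(structure)))
  within <- which(upper.tri(D) & D < cutoff, arr.ind = TRUE)
  ii <- within[, 1L]; jj <- within[, 2L]
  # backbone adjacency: consecutive residue numbers of the same chain
  # (a numbering gap means missing residues, hence no peptide bond)
  consec <- which(structure@chain[-n] == structure@chain[-1L] &
                    structure@resno[-1L] - structure@resno[-n] == 1L)
  covKey <- paste(consec, consec + 1L)
  key <- paste(ii, jj)
  keep <- !(key %in% covKey)
  ii <- ii[keep]; jj <- jj[keep]
  ci <- c(consec, ii); cj <- c(consec + 1L, jj)
  ct <- data.frame(
    i = ci, j = cj,
    dist = D[cbind(ci, cj)],
    gamma = c(rep(gammaCovalent, length(consec)),
              rep(gammaNoncovalent, length(ii))),
    kind = c(rep("covalent", length(consec)),
             rep("noncovalent", length(ii))))
  ct <- ct[order(ct$i, ct$j), , drop = FALSE]
  rownames(ct) <- NULL
  new("ElasticNetwork", structure = structure, contacts = ct,
      cutoff = as.numeric(cutoff))
}

#' @rdname contacts
#' @export
setMethod("contacts", "ElasticNetwork", function(x) x@contacts)

#' @rdname nNodes
#' @export
setMethod("nNodes", "ElasticNetwork", function(x) nNodes(x@structure))

setMethod("show", "ElasticNetwork", function(object) {
  ct <- object@contacts
  cat(sprintf("ElasticNetwork: %d nodes, %d contacts (%d covalent, %d noncovalent), cutoff %.1f A\n",
              nNodes(object), nrow(ct), sum(ct$kind == "covalent"),
              sum(ct$kind == "noncovalent"), object@cutoff))
  invisible(object)
})

# cheap content fingerprint of a network (provenance checking)
networkFingerprint <- function(network) {
  ct <- network@contacts
  xyz <- coords(network@structure)
  sprintf("N%d_c%d_%s_%s_%s",
          nNodes(network), nrow(ct),
          formatC(sum(ct$gamma * ct$dist), digits = 12, format = "g"),
          formatC(sum(xyz), digits = 12, format = "g"),
          formatC(sum(ct$i * 31 + ct$j), format = "d"))
}

#' ANM potential energy of a displaced configuration
#'
#' Evaluates V = 1/2 sum gamma_ij (r_ij - r_ij^0)^2 at arbitrary
#' coordinates, with the equilibrium distances taken from the network.
#' Mainly useful for validating the analytic Hessian against finite
#' differences.
#'
#' @param network an [ElasticNetwork-class].
#' @param xyz N x 3 coordinate matrix (default: the equilibrium
#'   coordinates, giving V = 0).
#' @return scalar energy in RT units.
#' @export
networkEnergy <- function(network, xyz = coords(network@structure)) {
  ct <- network@contacts
  d <- xyz[ct$i, , drop = FALSE] - xyz[ct$j, , drop = FALSE]
  r <- sqrt(rowSums(d * d))
  0.5 * sum(ct$gamma * (r - ct$dist)^2)
}

#' Build the 3N x 3N ANM Hessian
#'
#' Second derivative of the ANM potential at equilibrium. For each
#' contact (i, j) with separation vector d and distance r the
#' off-diagonal block is -(gamma/r^2) d d^T; diagonal blocks accumulate
#' the negatives of the off-diagonal blocks, so every block row sums to
#' zero (translation invariance).
#'
#' @param network an [ElasticNetwork-class].
#' @return symmetric 3N x 3N numeric matrix.
#' @export
buildHessian <- function(network) {
  s <- network@structure
  n <- nNodes(s)
  ct <- network@contacts
  if (any(ct$dist == 0))
    stop("coincident contact nodes (zero distance)", call. = FALSE)
  H <- matrix(0, 3L * n, 3L * n)
  xyz <- coords(s)
  for (k in seq_len(nrow(ct))) {
    i <- ct$i[k]; j <- ct$j[k]
    d <- xyz[i, ] - xyz[j, ]
    G <- (ct$gamma[k] / sum(d * d)) * tcrossprod(d)
    ri <- (3L * i - 2L):(3L * i); rj <- (3L * j - 2L):(3L * j)
    H[ri, rj] <- H[ri, rj] - G
    H[rj, ri] <- H[rj, ri] - G
    H[ri, ri] <- H[ri, ri] + G
    H[rj, rj] <- H[rj, rj] + G
  }
  H
}

#' Eigendecomposition of a Hessian with null-count contract
#'
#' Full symmetric eigendecomposition, eigenvalues ascending. An
#' eigenvalue counts as null iff it is below \code{tolRel * max(lambda)}.
#' Exactly six null modes (three translations, three rotations) are
#' required -- this is the package's connectivity contract; any other
#' count raises a classed error (\code{PerturbANM_connectivity_error})
#' reporting the count, since a network that is not one rigid connected
#' body silently corrupts every downstream quantity.
#'
#' @param hessian symmetric 3N x 3N matrix.
#' @param tolRel relative null tolerance (default 1e-8).
#' @param fingerprint provenance string stored in the result.
#' @return a [NetworkSpectrum-class].
#' @seealso [networkSpectrum()] for the network-level convenience wrapper.
#' @export
diagonalizeHessian <- function(hessian, tolRel = 1e-8, fingerprint = "") {
  e <- eigen(hessian, symmetric = TRUE)
  values <- rev(e$values)
  vectors <- e$vectors[, rev(seq_along(e$values)), drop = FALSE]
  nNull <- sum(values < tolRel * max(values))
  if (nNull != 6L) {
    cond <- structure(
      class = c("PerturbANM_connectivity_error", "error", "condition"),
      list(message = sprintf(
             "network is not a single rigid connected body: %d null modes (expected 6)",
             nNull),
           call = sys.call(-1L), nullCount = nNull))
    stop(cond)
  }
  new("NetworkSpectrum", values = values, vectors = vectors,
      nullCount = nNull, fingerprint = as.character(fingerprint))
}

#' Spectrum of an elastic network
#'
#' Convenience wrapper: builds the Hessian of the network, diagonalizes
#' it and stamps the result with the network's content fingerprint.
#'
#' @param network an [ElasticNetwork-class].
#' @param tolRel relative null tolerance passed to [diagonalizeHessian()].
#' @return a [NetworkSpectrum-class].
#' @export
networkSpectrum <- function(network, tolRel = 1e-8) {
  diagonalizeHessian(buildHessian(network), tolRel = tolRel,
                     fingerprint = networkFingerprint(network))
}

#' @rdname eigenValues
#' @export
setMethod("eigenValues", "NetworkSpectrum", function(x) x@values)

#' @rdname eigenVectors
#' @export
setMethod("eigenVectors", "NetworkSpectrum", function(x) x@vectors)

#' @rdname nullCount
#' @export
setMethod("nullCount", "NetworkSpectrum", function(x) x@nullCount)

setMethod("show", "NetworkSpectrum", function(object) {
  nm <- length(object@values)
  cat(sprintf("NetworkSpectrum: %d modes, %d null; softest non-null eigenvalue %.4g RT/A^2\n",
              nm, object@nullCount, object@values[object@nullCount + 1L]))
  invisible(object)
})

#' Moore-Penrose pseudoinverse of the Hessian (mechanical covariance)
#'
#' C = sum over non-null modes of (1/lambda_k) v_k v_k^T, kept in
#' factored form. C annihilates the six rigid-body modes and acts as the
#' inverse of the Hessian on their orthogonal complement; it encodes how
#' residues are dynamically coupled at equilibrium.
#'
#' @param spectrum a [NetworkSpectrum-class] with nullCount == 6.
#' @return a [MechCovariance-class].
#' @export
pseudoInverse <- function(spectrum) {
  stopifnot(is(spectrum, "NetworkSpectrum"))
  if (spectrum@nullCount != 6L)
    stop("pseudoinverse requires a 6-null-mode spectrum", call. = FALSE)
  keep <- (spectrum@nullCount + 1L):length(spectrum@values)
  new("MechCovariance",
      vectors = spectrum@vectors[, keep, drop = FALSE],
      invValues = 1 / spectrum@values[keep],
      fingerprint = spectrum@fingerprint)
}

#' @rdname operatorApply
#' @export
setMethod("operatorApply", "MechCovariance", function(x, v) {
  drop(x@vectors %*% (x@invValues * crossprod(x@vectors, v)))
})

#' @rdname asMatrix
#' @export
setMethod("asMatrix", "MechCovariance", function(x) {
  x@vectors %*% (x@invValues * t(x@vectors))
})

setMethod("show", "MechCovariance", function(object) {
  cat(sprintf("MechCovariance: factored pseudoinverse, %d non-null modes, dim %d\n",
              length(object@invValues), nrow(object@vectors)))
  invisible(object)
})

#' Serialize a network's contact list as TSV
#'
#' Edge list with node indices, chain/residue labels, equilibrium
#' distance, spring constant and kind.
#'
#' @param network an [ElasticNetwork-class].
#' @param path output TSV path.
#' @return invisibly, the path.
#' @export
writeNetworkTSV <- function(network, path) {
  s <- network@structure
  ct <- network@contacts
  df <- data.frame(i = ct$i, j = ct$j,
                   chain_i = s@chain[ct$i], res_i = s@resno[ct$i],
                   chain_j = s@chain[ct$j], res_j = s@resno[ct$j],
                   distance = ct$dist, gamma = ct$gamma, kind = ct$kind)
  utils::write.table(format(df, digits = 10), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
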