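## Contact switch-off gedankenexperiment.
##
## Every noncovalent contact class (orbit under the cyclic chain
## permutation A->B->C->D) is removed in all four subunits
## simultaneously, the linear response is recomputed, and the change in
## the per-residue displacement field is scored. Backbone (covalent)
## springs are never switched off: that would model chain scission, not
## contact loss.
##
## Fast path: removing the class's m springs is a rank-m downdate
## H' = H - U U^T whose columns (sqrt(gamma) times the +-unit-separation
## pattern) are orthogonal to all six rigid-body modes, so the
## pseudoinverse updates by a range-restricted Woodbury identity
##   C' f = C f + C U (I - U^T C U)^{-1} U^T C f,
## and a singular capacitance matrix I - U^T C U signals that the
## removal disconnects the network.

#' Group noncovalent contacts into C4 symmetry classes
#'
#' Contacts are mapped under the chain rotation A->B->C->D (same residue
#' numbers, next chain) and grouped into orbits. On an exactly symmetric
#' contact map every class has 4 members, except contacts between
#' opposite subunits whose orbit has 2; a missing symmetry mate produces
#' a warning and a smaller class. Classes partition the noncovalent
#' contacts (asserted).
#'
#' @param network an [ElasticNetwork-class] whose structure is a tetramer.
#' @return a [ContactClassSet-class].
#' @export
enumerateContactClasses <- function(network) {
  s <- network@structure
  assertTetramer(s, "contact-class enumeration")
  ch <- chainLevels(s)
  ct <- contacts(network)
  nc <- which(ct$kind == "noncovalent")
  key <- paste(ct$i, ct$j)
  lookupContact <- function(i, j) match(paste(i, j), key)
  # node under chain rotation: same resno, next chain
  chainPos <- match(s@chain, ch)
  rotNode <- function(i, k) {
    nodeIndex(s, ch[((chainPos[i] - 1L + k) %% 4L) + 1L], s@resno[i])
  }
  assigned <- integer(0L)
  classes <- list(); members <- list()
  cid <- 0L
  for (row in nc) {
    if (row %in% assigned) next
    cid <- cid + 1L
    i0 <- ct$i[row]; j0 <- ct$j[row]
    orbit <- unique(t(vapply(0:3, function(k) {
      a <- rotNode(i0, k); b <- rotNode(j0, k)
      c(min(a, b), max(a, b))
    }, integer(2L))))
    rows <- lookupContact(orbit[, 1L], orbit[, 2L])
    if (anyNA(rows)) {
      warning(sprintf("contact class %d: %d symmetry mate(s) absent from contact map",
                      cid, sum(is.na(rows))), call. = FALSE)
      orbit <- orbit[!is.na(rows), , drop = FALSE]
      rows <- rows[!is.na(rows)]
    }
    assigned <- c(assigned, rows)
    # representative: lexicographically smallest member
    repRow <- orbit[order(orbit[, 1L], orbit[, 2L])[1L], ]
    classes[[cid]] <- data.frame(
      classId = cid,
      chainI = s@chain[repRow[1L]], resI = s@resno[repRow[1L]],
      chainJ = s@chain[repRow[2L]], resJ = s@resno[repRow[2L]],
      kind = if (s@chain[i0] == s@chain[j0]) "intra-subunit" else "inter-subunit",
      nMembers = nrow(orbit))
    members[[cid]] <- data.frame(classId = cid, i = orbit[, 1L], j = orbit[, 2L])
  }
  classesDf <- do.call(rbind, classes)
  membersDf <- do.call(rbind, members)
  # partition check: disjoint cover of the noncovalent contacts
  covered <- sort(lookupContact(membersDf$i, membersDf$j))
  if (anyDuplicated(covered) || !identical(covered, sort(nc)))
    stop("internal error: classes do not partition the noncovalent contacts")
  new("ContactClassSet", classes = classesDf, members = membersDf,
      fingerprint = networkFingerprint(network))
}

setMethod("show", "ContactClassSet", function(object) {
  cat(sprintf("ContactClassSet: %d classes (%d intra-, %d inter-subunit), %d member contacts\n",
              nrow(object@classes),
              sum(object@classes$kind == "intra-subunit"),
              sum(object@classes$kind == "inter-subunit"),
              nrow(object@members)))
  invisible(object)
})

# columns of the rank-m downdate for the given member springs
switchOffUpdateMatrix <- function(network, memberRows) {
  ct <- network@contacts
  xyz <- coords(network@structure)
  n3 <- 3L * nNodes(network@structure)
  U <- matrix(0, n3, length(memberRows))
  for (c0 in seq_along(memberRows)) {
    k <- memberRows[c0]
    i <- ct$i[k]; j <- ct$j[k]
    d <- xyz[i, ] - xyz[j, ]
    dhat <- d / sqrt(sum(d * d))
    g <- sqrt(ct$gamma[k])
    U[(3L * i - 2L):(3L * i), c0] <- g * dhat
    U[(3L * j - 2L):(3L * j), c0] <- -g * dhat
  }
  U
}

# match contact-table rows for a members data.frame(i, j)
memberRowIndices <- function(network, members) {
  ct <- network@contacts
  rows <- match(paste(members$i, members$j), paste(ct$i, ct$j))
  if (anyNA(rows)) stop("class member not present in network", call. = FALSE)
  if (any(ct$kind[rows] == "covalent"))
    stop("covalent springs are not eligible for switch-off", call. = FALSE)
  rows
}

#' Linear response with one contact class switched off
#'
#' Removes the class's springs from the network and recomputes the LRT
#' displacement. Two routes: \code{"woodbury"} (default) updates the
#' factored pseudoinverse by a low-rank identity; \code{"rebuild"}
#' reconstructs Hessian, spectrum and pseudoinverse from scratch. Both
#' agree to high precision; the rebuild route serves as the reference.
#' If the removal disconnects the network (more than six null modes) the
#' result is flagged \code{disconnecting} and carries no response.
#'
#' @param network the baseline [ElasticNetwork-class].
#' @param members data.frame(i, j) of the springs to remove (a class's
#'   \code{members} rows, without the classId column restriction --
#'   extra columns are ignored).
#' @param force the [ForceVector-class] to apply.
#' @param covariance baseline [MechCovariance-class]; required for the
#'   Woodbury route (computed if missing).
#' @param method "woodbury" or "rebuild".
#' @param singTol relative singularity tolerance for the capacitance
#'   matrix (disconnection detection).
#' @return list(response = [LRTResponse-class] or NULL,
#'   disconnecting = logical).
#' @export
switchOffResponse <- function(network, members, force, covariance = NULL,
                              method = c("woodbury", "rebuild"),
                              singTol = 1e-8) {
  method <- match.arg(method)
  rows <- memberRowIndices(network, members)
  if (method == "rebuild") {
    net2 <- network
    net2@contacts <- network@contacts[-rows, , drop = FALSE]
    spec2 <- tryCatch(networkSpectrum(net2), PerturbANM_connectivity_error = identity)
    if (inherits(spec2, "condition"))
      return(list(response = NULL, disconnecting = TRUE))
    resp <- lrtResponse(pseudoInverse(spec2), force)
    resp@fingerprint <- networkFingerprint(network)  # report against baseline
    return(list(response = resp, disconnecting = FALSE))
  }
  if (is.null(covariance))
    covariance <- pseudoInverse(networkSpectrum(network))
  U <- switchOffUpdateMatrix(network, rows)
  CU <- apply(U, 2L, function(u) operatorApply(covariance, u))
  S <- diag(ncol(U)) - crossprod(U, CU)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < singTol * max(abs(ev), 1))
    return(list(response = NULL, disconnecting = TRUE))
  Cf <- operatorApply(covariance, force@f)
  dr <- force@beta * (Cf + drop(CU %*% solve(S, crossprod(U, Cf))))
  resp <- new("LRTResponse", deltaR = dr, magnitudes = vectorMagnitudes(dr),
              force = force, fingerprint = covariance@fingerprint)
  list(response = resp, disconnecting = FALSE)
}

#' Screen all contact classes by symmetric switch-off
#'
#' For every noncovalent contact class: remove its springs in all
#' subunits, recompute the response, normalize baseline and perturbed
#' per-residue magnitude vectors by the baseline's maximum magnitude
#' (LRT units are arbitrary, so the change threshold is expressed as a
#' fraction of the peak baseline displacement), and count per subunit
#' the residues whose |change| strictly exceeds \code{deltaThreshold}.
#' A class is significant iff every subunit's count is at least
#' \code{minResidues}. Records are sorted by the minimum per-subunit
#' count (descending); ties broken by the representative pair's
#' (chain, residue, residue) order. Disconnecting removals are flagged
#' and never scored.
#'
#' @param network baseline [ElasticNetwork-class] (tetramer).
#' @param force the perturbing [ForceVector-class].
#' @param deltaThreshold significance threshold on the normalized
#'   per-residue magnitude change (default 0.1).
#' @param minResidues minimum number of affected residues required in
#'   each subunit (default 15).
#' @param method per-class solver passed to [switchOffResponse()].
#' @param classSet optional precomputed [ContactClassSet-class].
#' @param covariance optional precomputed baseline covariance.
#' @return data.frame with one row per class: representative pair, kind,
#'   per-subunit counts, minCount, disconnecting, significant.
#' @export
screenContacts <- function(network, force, deltaThreshold = 0.1,
                           minResidues = 15L,
                           method = c("woodbury", "rebuild"),
                           classSet = NULL, covariance = NULL) {
  method <- match.arg(method)
  s <- network@structure
  assertTetramer(s, "switch-off screening")
  if (is.null(classSet)) classSet <- enumerateContactClasses(network)
  if (is.null(covariance)) covariance <- pseudoInverse(networkSpectrum(network))
  base <- lrtResponse(covariance, force)
  norm0 <- max(base@magnitudes)
  m0 <- if (norm0 > 0) base@magnitudes / norm0 else base@magnitudes
  chains <- chainLevels(s)
  chainOf <- match(s@chain, chains)
  cls <- classSet@classes
  nCls <- nrow(cls)
  counts <- matrix(0L, nCls, 4L, dimnames = list(NULL, chains))
  disconnecting <- logical(nCls)
  for (k in seq_len(nCls)) {
    mem <- classSet@members[classSet@members$classId == cls$classId[k], ]
    res <- switchOffResponse(network, mem, force, covariance = covariance,
                             method = method)
    if (res$disconnecting) { disconnecting[k] <- TRUE; next }
    m1 <- if (norm0 > 0) res$response@magnitudes / norm0 else res$response@magnitudes
    dm <- abs(m1 - m0)
    hit <- dm > deltaThreshold
    counts[k, ] <- vapply(1:4, function(q) sum(hit[chainOf == q]), integer(1L))
  }
  out <- cbind(cls,
               as.data.frame(counts),
               minCount = apply(counts, 1L, min),
               disconnecting = disconnecting)
  out$minCount[disconnecting] <- NA_integer_
  out$significant <- !disconnecting & apply(counts, 1L, min) >= minResidues
  ord <- order(disconnecting, -ifelse(is.na(out$minCount), -1L, out$minCount),
               out$chainI, out$resI, out$resJ)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a switch-off screen as TSV
#'
#' @param screen output of [screenContacts()].
#' @param path output TSV path.
#' @return invisibly, the path.
#' @export
writeScreenTSV <- function(screen, path) {
  utils::write.table(screen, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
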