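## Linear response theory: delta_r = beta * C * F.
##
## Forces are pure direction fields: every targeted residue carries a
## unit 3-vector, everything else zero, and the scalar beta carries the
## (arbitrary) strength. Displacement magnitudes are therefore shape-only
## -- only ratios between residues are meaningful.

#' Binding-pocket opening force
#'
#' Unit force on each pocket residue pointing from the pseudo-ligand
#' center towards that residue's Calpha (the direction a dissociating
#' ligand pushes the pocket open). All per-residue force vectors are
#' normalized to the same (unit) length. For a tetramer the same pocket
#' residues are forced in every chain, each chain using its own ligand
#' center (computed by [pocketCentroid()] when not supplied).
#'
#' @param structure a [CaStructure-class].
#' @param pocketResidues residue numbers of the pocket (per chain).
#' @param ligandCenters optional matrix of ligand centers, one row per
#'   targeted chain (rownames = chain ids), or a single length-3 vector
#'   when one chain is targeted. Default: [pocketCentroid()] per chain.
#' @param chains chains to force (default all).
#' @param beta force constant (arbitrary units; default 1). Sign mimics
#'   binding vs unbinding; the default +1 opens the pocket.
#' @return a [ForceVector-class].
#' @export
bindingPocketForce <- function(structure, pocketResidues,
                               ligandCenters = NULL,
                               chains = chainLevels(structure),
                               beta = 1) {
  stopifnot(is(structure, "CaStructure"))
  if (is.null(ligandCenters)) {
    ligandCenters <- t(vapply(chains, function(ch)
      pocketCentroid(structure, ch, pocketResidues), numeric(3L)))
  } else if (is.null(dim(ligandCenters))) {
    stopifnot(length(chains) == 1L)
    ligandCenters <- matrix(ligandCenters, nrow = 1L,
                            dimnames = list(chains, NULL))
  }
  f <- numeric(3L * nNodes(structure))
  xyz <- coords(structure)
  for (k in seq_along(chains)) {
    ctr <- ligandCenters[k, ]
    idx <- nodeIndex(structure, chains[k], pocketResidues)
    for (i in idx) {
      d <- xyz[i, ] - ctr
      nd <- sqrt(sum(d * d))
      if (nd < 1e-9)
        stop(sprintf("ligand center coincides with pocket residue %s:%d",
                     chains[k], structure@resno[i]), call. = FALSE)
      f[(3L * i - 2L):(3L * i)] <- d / nd
    }
  }
  new("ForceVector", f = f, beta = as.numeric(beta),
      description = sprintf("pocket[%s] on chains %s",
                            paste(pocketResidues, collapse = ","),
                            paste(chains, collapse = "")))
}

#' Voltage-mimicking force on charged residues
#'
#' A transmembrane field along \code{axis} pushes each formally charged
#' residue with unit magnitude: force = sign(charge) * axis. Only the
#' direction convention matters at the qualitative level of linear
#' response; magnitudes are not weighted by |charge|, consistent with
#' the equal-length normalization of the pocket force.
#'
#' @param structure a [CaStructure-class] carrying charge annotations
#'   (see [assignFormalCharges()]).
#' @param beta force constant (default 1).
#' @param axis field axis, normalized internally (default membrane
#'   normal, +z).
#' @return a [ForceVector-class].
#' @export
voltageForce <- function(structure, beta = 1, axis = c(0, 0, 1)) {
  stopifnot(is(structure, "CaStructure"))
  axis <- axis / sqrt(sum(axis^2))
  q <- charges(structure)
  charged <- which(q != 0L)
  if (!length(charged))
    stop("no charged residues in structure", call. = FALSE)
  f <- numeric(3L * nNodes(structure))
  for (i in charged)
    f[(3L * i - 2L):(3L * i)] <- sign(q[i]) * axis
  new("ForceVector", f = f, beta = as.numeric(beta),
      description = sprintf("voltage axis (%s), %d charged residues",
                            paste(format(axis, digits = 3), collapse = ","),
                            length(charged)))
}

#' Linear-response displacement to a force
#'
#' delta_r = beta * C * F: the expected coordinate shift of every residue
#' given the equilibrium mechanical covariance C of the unperturbed
#' network. Output units are arbitrary.
#'
#' @param covariance a [MechCovariance-class] (6-null-mode provenance).
#' @param force a [ForceVector-class] of matching dimension.
#' @return an [LRTResponse-class].
#' @export
lrtResponse <- function(covariance, force) {
  stopifnot(is(covariance, "MechCovariance"), is(force, "ForceVector"))
  if (length(force@f) != nrow(covariance@vectors))
    stop(sprintf("dimension mismatch: force %d vs covariance %d",
                 length(force@f), nrow(covariance@vectors)), call. = FALSE)
  dr <- force@beta * operatorApply(covariance, force@f)
  new("LRTResponse", deltaR = dr, magnitudes = vectorMagnitudes(dr),
      force = force, fingerprint = covariance@fingerprint)
}

#' @rdname magnitudes
#' @export
setMethod("magnitudes", "LRTResponse", function(x) x@magnitudes)

setMethod("show", "LRTResponse", function(object) {
  cat(sprintf("LRTResponse: %d residues, peak |dr| %.4g (arbitrary units)\n  force: %s (beta = %g)\n",
              length(object@magnitudes), max(object@magnitudes),
              object@force@description, object@force@beta))
  invisible(object)
})

#' Per-residue displacement profile
#'
#' Tabulates the Euclidean displacement magnitude of every residue
#' (arbitrary units), optionally restricted to one chain -- the
#' per-subunit profile of the response.
#'
#' @param response an [LRTResponse-class].
#' @param structure the matching [CaStructure-class].
#' @param chain optional chain to restrict to.
#' @return data.frame(chain, resno, magnitude).
#' @export
displacementProfile <- function(response, structure, chain = NULL) {
  stopifnot(is(response, "LRTResponse"), is(structure, "CaStructure"))
  if (length(response@magnitudes) != nNodes(structure))
    stop("response and structure sizes disagree", call. = FALSE)
  df <- data.frame(chain = structure@chain, resno = structure@resno,
                   magnitude = response@magnitudes)
  if (!is.null(chain)) df <- df[df$chain == chain, , drop = FALSE]
  rownames(df) <- NULL
  df
}
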