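#' @import methods
NULL

#' Calpha-resolution protein structure
#'
#' One node per residue: chain identifier, residue number (as given in the
#' source PDB, preserved for all reporting), three-letter residue name,
#' Calpha coordinates in Angstrom and an optional integer formal charge.
#' Nodes are ordered by chain (in order of first appearance) and then by
#' residue number; node \code{i} maps to rows \code{3i-2..3i} of any
#' 3N-dimensional vector or matrix used elsewhere in the package.
#'
#' @slot chain character vector of chain identifiers, one per node.
#' @slot resno integer residue numbers (source numbering preserved).
#' @slot resname three-letter residue names.
#' @slot xyz N x 3 numeric matrix of Calpha coordinates (Angstrom).
#' @slot charge integer formal charges in elementary charge units.
#'
#' @seealso [CaStructure()] for the user-facing constructor,
#'   [generateC4Tetramer()] for synthetic tetramers.
#' @exportClass CaStructure
setClass("CaStructure",
  slots = c(
    chain   = "character",
    resno   = "integer",
    resname = "character",
    xyz     = "matrix",
    charge  = "integer"
  )
)

setValidity("CaStructure", function(object) {
  n <- length(object@chain)
  if (n == 0L) return("structure must contain at least one residue")
  if (length(object@resno) != n || length(object@resname) != n ||
      length(object@charge) != n || nrow(object@xyz) != n)
    return("slot lengths disagree")
  if (ncol(object@xyz) != 3L) return("xyz must have 3 columns")
  if (!all(is.finite(object@xyz))) return("non-finite coordinates")
  key <- paste(object@chain, object@resno)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1L]
    return(sprintf("duplicate (chain, residue) pair: %s", dup))
  }
  TRUE
})

#' Elastic network (ANM) built on a CaStructure
#'
#' Holds the structure together with the contact list of the anisotropic
#' network model. Each contact carries its node pair (i < j), equilibrium
#' distance, spring constant gamma (RT/Angstrom^2) and kind:
#' \code{"covalent"} for chain-consecutive backbone pairs (included
#' regardless of distance), \code{"noncovalent"} for any other pair closer
#' than the cutoff.
#'
#' @slot structure a [CaStructure-class].
#' @slot contacts data.frame with columns i, j, dist, gamma, kind.
#' @slot cutoff numeric contact cutoff in Angstrom.
#' @exportClass ElasticNetwork
setClass("ElasticNetwork",
  slots = c(
    structure = "CaStructure",
    contacts  = "data.frame",
    cutoff    = "numeric"
  )
)

setValidity("ElasticNetwork", function(object) {
  ct <- object@contacts
  need <- c("i", "j", "dist", "gamma", "kind")
  if (!all(need %in% names(ct))) return("contacts must have columns i, j, dist, gamma, kind")
  if (nrow(ct)) {
    if (any(ct$i >= ct$j)) return("contacts must satisfy i < j")
    if (anyDuplicated(paste(ct$i, ct$j))) return("duplicate contacts")
    if (any(ct$gamma <= 0)) return("spring constants must be positive")
    if (!all(ct$kind %in% c("covalent", "noncovalent")))
      return("contact kind must be covalent or noncovalent")
  }
  TRUE
})

#' Eigendecomposition of an ANM Hessian
#'
#' Eigenvalues in ascending order (units RT/Angstrom^2) with orthonormal
#' eigenvectors as columns, plus the number of numerically null modes.
#' For a single rigid connected body the null count is exactly six
#' (three translations, three rotations).
#'
#' @slot values ascending numeric eigenvalues.
#' @slot vectors 3N x 3N matrix, eigenvectors in columns.
#' @slot nullCount integer number of null modes.
#' @slot fingerprint content fingerprint of the generating network.
#' @exportClass NetworkSpectrum
setClass("NetworkSpectrum",
  slots = c(
    values      = "numeric",
    vectors     = "matrix",
    nullCount   = "integer",
    fingerprint = "character"
  )
)

#' Mechanical covariance (Moore-Penrose pseudoinverse of the Hessian)
#'
#' Kept in factored form: the non-null eigenvectors and the reciprocals of
#' their eigenvalues, so that C f = V diag(1/lambda) V^T f is applied
#' without materializing the 3N x 3N matrix. Annihilates the six
#' rigid-body modes and inverts the Hessian on their orthogonal
#' complement.
#'
#' @slot vectors 3N x (3N-6) matrix of non-null eigenvectors.
#' @slot invValues reciprocals of the non-null eigenvalues.
#' @slot fingerprint content fingerprint of the generating network.
#' @exportClass MechCovariance
setClass("MechCovariance",
  slots = c(
    vectors     = "matrix",
    invValues   = "numeric",
    fingerprint = "character"
  )
)

#' Perturbing force vector
#'
#' A 3N direction field (unit per-residue force on every targeted residue,
#' zero elsewhere) plus the scalar force constant beta. Magnitudes carry
#' arbitrary units throughout: linear response is qualitative and only
#' ratios of displacements are meaningful.
#'
#' @slot f 3N numeric force direction vector.
#' @slot beta positive scalar force constant (arbitrary units).
#' @slot description provenance label.
#' @exportClass ForceVector
setClass("ForceVector",
  slots = c(
    f           = "numeric",
    beta        = "numeric",
    description = "character"
  )
)

setValidity("ForceVector", function(object) {
  if (length(object@f) %% 3L != 0L) return("force length must be a multiple of 3")
  if (length(object@beta) != 1L || !is.finite(object@beta))
    return("beta must be a finite scalar")
  TRUE
})

#' Linear-response displacement
#'
#' The expected coordinate shift delta r = beta C F for a force F applied
#' to the equilibrium network, together with per-residue Euclidean
#' magnitudes. Units are arbitrary.
#'
#' @slot deltaR 3N displacement vector.
#' @slot magnitudes per-residue Euclidean norms (length N).
#' @slot force the generating [ForceVector-class].
#' @slot fingerprint content fingerprint of the generating network.
#' @exportClass LRTResponse
setClass("LRTResponse",
  slots = c(
    deltaR      = "numeric",
    magnitudes  = "numeric",
    force       = "ForceVector",
    fingerprint = "character"
  )
)

#' Symmetry classes of noncovalent contacts
#'
#' Noncovalent contacts of a C4 tetramer grouped into orbits under the
#' cyclic chain permutation A->B->C->D. \code{classes} has one row per
#' class (representative pair, kind, member count), \code{members} maps
#' every contact to its class. Classes partition the noncovalent contacts.
#'
#' @slot classes data.frame: classId, chainI, resI, chainJ, resJ, kind, nMembers.
#' @slot members data.frame: classId, i, j (node indices).
#' @slot fingerprint content fingerprint of the generating network.
#' @exportClass ContactClassSet
setClass("ContactClassSet",
  slots = c(
    classes     = "data.frame",
    members     = "data.frame",
    fingerprint = "character"
  )
)

#' Best linear combination of modes for a target displacement
#'
#' @slot modes global indices (ascending-eigenvalue, 1-based after the six
#'   null modes) of the selected non-degenerate modes.
#' @slot coefficients projections of the normalized target on the modes.
#' @slot combined the 3N combined vector.
#' @slot overlap absolute cosine between combined vector and target.
#' @exportClass ModeCombination
setClass("ModeCombination",
  slots = c(
    modes        = "integer",
    coefficients = "numeric",
    combined     = "numeric",
    overlap      = "numeric"
  )
)
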