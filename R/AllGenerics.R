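#' Number of residue nodes
#' @param x a PerturbANM object.
#' @return integer node count N.
#' @export
setGeneric("nNodes", function(x) standardGeneric("nNodes"))

#' Chain identifiers in order of first appearance
#' @param x a PerturbANM object.
#' @return character vector of unique chain ids.
#' @export
setGeneric("chainLevels", function(x) standardGeneric("chainLevels"))

#' Calpha coordinate matrix
#' @param x a PerturbANM object.
#' @return N x 3 numeric matrix (Angstrom).
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))

#' Formal charges per residue
#' @param x a PerturbANM object.
#' @return integer vector of length N.
#' @export
setGeneric("charges", function(x) standardGeneric("charges"))

#' Contact table of an elastic network
#' @param x an [ElasticNetwork-class].
#' @return data.frame with columns i, j, dist, gamma, kind.
#' @export
setGeneric("contacts", function(x) standardGeneric("contacts"))

#' Eigenvalues of a network spectrum
#' @param x a [NetworkSpectrum-class].
#' @return ascending numeric eigenvalues.
#' @export
setGeneric("eigenValues", function(x) standardGeneric("eigenValues"))

#' Eigenvectors of a network spectrum
#' @param x a [NetworkSpectrum-class].
#' @return 3N x 3N matrix with eigenvectors in columns.
#' @export
setGeneric("eigenVectors", function(x) standardGeneric("eigenVectors"))

#' Number of numerically null (rigid-body) modes
#' @param x a [NetworkSpectrum-class].
#' @return integer.
#' @export
setGeneric("nullCount", function(x) standardGeneric("nullCount"))

#' Apply an operator to a vector
#' @param x an operator object (e.g. [MechCovariance-class]).
#' @param v numeric vector of matching dimension.
#' @return numeric vector.
#' @export
setGeneric("operatorApply", function(x, v) standardGeneric("operatorApply"))

#' Materialize an operator as a dense matrix
#' @param x an operator object.
#' @return square numeric matrix.
#' @export
setGeneric("asMatrix", function(x) standardGeneric("asMatrix"))

#' Per-residue displacement magnitudes
#' @param x an [LRTResponse-class].
#' @return numeric vector of length N (arbitrary units).
#' @export
setGeneric("magnitudes", function(x) standardGeneric("magnitudes"))
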