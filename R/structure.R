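#' Construct a CaStructure
#'
#' Builds the package's central Calpha container. Nodes are sorted into
#' the canonical order (chains in order of first appearance, then residue
#' number); sorting is idempotent, so constructing from already-ordered
#' input is a no-op.
#'
#' @param chain character chain identifiers, one per residue.
#' @param resno integer residue numbers (source numbering, preserved in
#'   all reports).
#' @param resname three-letter residue names (recycled if length 1).
#' @param xyz N x 3 coordinate matrix in Angstrom.
#' @param charge integer formal charges (default all zero).
#' @return a [CaStructure-class].
#' @examples
#' s <- CaStructure(chain = c("A", "A"), resno = 1:2,
#'                  resname = "ALA", xyz = rbind(c(0, 0, 0), c(3.8, 0, 0)))
#' nNodes(s)
#' @export
CaStructure <- function(chain, resno, resname, xyz, charge = NULL) {
  xyz <- as.matrix(xyz)
  storage.mode(xyz) <- "double"
  n <- nrow(xyz)
  if (length(chain) == 1L) chain <- rep(chain, n)
  if (length(resname) == 1L) resname <- rep(resname, n)
  if (is.null(charge)) charge <- integer(n)
  ord <- order(match(chain, unique(chain)), resno)
  new("CaStructure",
      chain = as.character(chain)[ord], resno = as.integer(resno)[ord],
      resname = as.character(resname)[ord], xyz = xyz[ord, , drop = FALSE],
      charge = as.integer(charge)[ord])
}

#' @rdname nNodes
#' @export
setMethod("nNodes", "CaStructure", function(x) length(x@chain))

#' @rdname chainLevels
#' @export
setMethod("chainLevels", "CaStructure", function(x) unique(x@chain))

#' @rdname coords
#' @export
setMethod("coords", "CaStructure", function(x) x@xyz)

#' @rdname charges
#' @export
setMethod("charges", "CaStructure", function(x) x@charge)

#' Residue table of a structure
#'
#' @param x a [CaStructure-class].
#' @return data.frame with columns chain, resno, resname, x, y, z, charge.
#' @export
residueTable <- function(x) {
  stopifnot(is(x, "CaStructure"))
  data.frame(chain = x@chain, resno = x@resno, resname = x@resname,
             x = x@xyz[, 1L], y = x@xyz[, 2L], z = x@xyz[, 3L],
             charge = x@charge, stringsAsFactors = FALSE)
}

#' @describeIn CaStructure subset residues by node index, preserving order.
#' @param x,i object and index.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "CaStructure", function(x, i, j, ..., drop = FALSE) {
  new("CaStructure", chain = x@chain[i], resno = x@resno[i],
      resname = x@resname[i], xyz = x@xyz[i, , drop = FALSE],
      charge = x@charge[i])
})

setMethod("show", "CaStructure", function(object) {
  ch <- chainLevels(object)
  cat(sprintf("CaStructure: %d residues, %d chain(s) [%s]\n",
              nNodes(object), length(ch),
              paste(ch, collapse = ", ")))
  nq <- sum(object@charge != 0L)
  if (nq) cat(sprintf("  %d residues carry formal charge\n", nq))
  invisible(object)
})

#' Test fourfold (tetramer) organisation of a structure
#'
#' A structure qualifies for the tetramer-specific operations when it has
#' exactly four chains of equal length with identical residue-name
#' sequences. Coordinates are deliberately not compared: homology models
#' have symmetric sequence but asymmetric coordinates.
#'
#' @param x a [CaStructure-class].
#' @return logical scalar.
#' @export
isC4Tetramer <- function(x) {
  stopifnot(is(x, "CaStructure"))
  ch <- chainLevels(x)
  if (length(ch) != 4L) return(FALSE)
  seqs <- split(x@resname, factor(x@chain, levels = ch))
  lens <- lengths(seqs)
  if (length(unique(lens)) != 1L) return(FALSE)
  all(vapply(seqs[-1L], identical, logical(1L), y = seqs[[1L]]))
}

assertTetramer <- function(x, what = "this operation") {
  if (!isC4Tetramer(x))
    stop(what, " requires a tetramer: exactly 4 chains of equal length ",
         "with identical residue-name sequences", call. = FALSE)
  invisible(TRUE)
}

#' Look up node indices of residues
#'
#' @param x a [CaStructure-class].
#' @param chain chain identifier(s), recycled against \code{resno}.
#' @param resno residue number(s).
#' @return integer node indices; error if any residue is absent.
#' @export
nodeIndex <- function(x, chain, resno) {
  key <- paste(x@chain, x@resno)
  idx <- match(paste(chain, resno), key)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1L]
    stop(sprintf("residue %s:%s not present in structure",
                 rep(chain, length.out = length(resno))[bad], resno[bad]),
         call. = FALSE)
  }
  idx
}

#' Assign standard formal charges from residue names
#'
#' ARG and LYS receive +1, ASP and GLU -1, all other residues (including
#' HIS) 0 -- the standard formal charges at neutral pH. Existing charges
#' are overwritten unless \code{keep = TRUE}.
#'
#' @param x a [CaStructure-class].
#' @param keep if TRUE, only residues with charge 0 are (re)assigned.
#' @return the structure with updated charges.
#' @export
assignFormalCharges <- function(x, keep = FALSE) {
  stopifnot(is(x, "CaStructure"))
  q <- integer(nNodes(x))
  q[x@resname %in% c("ARG", "LYS")] <- 1L
  q[x@resname %in% c("ASP", "GLU")] <- -1L
  if (keep) q[x@charge != 0L] <- x@charge[x@charge != 0L]
  x@charge <- q
  x
}

# Dense per-node -> 3N row indices (node i <-> rows 3i-2..3i).
nodeRows <- function(i) {
  as.vector(rbind(3L * i - 2L, 3L * i - 1L, 3L * i))
}

# Per-node Euclidean magnitudes of a 3N vector.
vectorMagnitudes <- function(v) {
  m <- matrix(v, nrow = 3L)
  sqrt(colSums(m * m))
}
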