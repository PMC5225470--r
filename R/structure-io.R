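#' Read a Calpha structure from a PDB file
#'
#' Parses ATOM records (via bio3d) and keeps one node per residue: the CA
#' atom, first ALTLOC if several are present. HETATM records are ignored.
#' Files with insertion codes are rejected; multi-model files use MODEL 1
#' only, with a warning. A residue that has ATOM records but no CA atom is
#' an error naming the residue.
#'
#' @param path PDB file.
#' @param chargePath optional sidecar TSV (columns chain, resno, charge)
#'   carrying formal charges, which the PDB format cannot hold.
#' @return a [CaStructure-class].
#' @seealso [writePDBCa()]
#' @export
readPDBCa <- function(path, chargePath = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  nModel <- sum(startsWith(lines, "MODEL"))
  if (nModel > 1L) {
    warning("multi-model PDB: using MODEL 1 only", call. = FALSE)
    endIdx <- which(startsWith(lines, "ENDMDL"))[1L]
    tmp <- tempfile(fileext = ".pdb")
    on.exit(unlink(tmp), add = TRUE)
    writeLines(lines[seq_len(endIdx)], tmp)
    path <- tmp
  }
  pdb <- bio3d::read.pdb(path, rm.alt = TRUE, verbose = FALSE)
  atoms <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(atoms) == 0L) stop("no parseable ATOM records in ", path, call. = FALSE)
  if (any(!is.na(atoms$insert) & atoms$insert != ""))
    stop("insertion codes are not supported", call. = FALSE)
  atoms$chain[is.na(atoms$chain)] <- " "
  key <- paste(atoms$chain, atoms$resno)
  isCA <- atoms$elety == "CA"
  noCA <- setdiff(unique(key), unique(key[isCA]))
  if (length(noCA)) {
    bad <- strsplit(noCA[1L], " ", fixed = TRUE)[[1L]]
    stop(sprintf("residue %s:%s has no CA atom", bad[1L], bad[2L]), call. = FALSE)
  }
  ca <- atoms[isCA, , drop = FALSE]
  ca <- ca[!duplicated(paste(ca$chain, ca$resno)), , drop = FALSE]  # first ALTLOC
  s <- CaStructure(chain = ca$chain, resno = ca$resno, resname = ca$resid,
                   xyz = cbind(ca$x, ca$y, ca$z))
  if (!is.null(chargePath)) {
    qt <- utils::read.delim(chargePath, stringsAsFactors = FALSE)
    idx <- nodeIndex(s, qt$chain, qt$resno)
    q <- integer(nNodes(s))
    q[idx] <- as.integer(qt$charge)
    s@charge <- q
  }
  s
}

#' Write a Calpha structure as PDB
#'
#' Emits standard ATOM records, CA atoms only, occupancy 1.00. The
#' B-factor column may carry a per-residue scalar (e.g. a displacement
#' magnitude), rescaled to [0, 99.99]. Formal charges have no PDB field
#' and are written to a sidecar TSV when present or requested.
#'
#' @param x a [CaStructure-class].
#' @param path output PDB path.
#' @param bfactor optional numeric length-N vector written (rescaled) to
#'   the B-factor column.
#' @param chargePath sidecar TSV path for charges; defaults to
#'   \code{<path>.charges.tsv} when any charge is nonzero.
#' @return invisibly, the PDB path.
#' @export
writePDBCa <- function(x, path, bfactor = NULL, chargePath = NULL) {
  stopifnot(is(x, "CaStructure"))
  n <- nNodes(x)
  b <- rep(0, n)
  if (!is.null(bfactor)) {
    stopifnot(length(bfactor) == n)
    top <- max(abs(bfactor))
    if (top > 0) b <- 99.99 * abs(bfactor) / top
  }
  bio3d::write.pdb(file = path, xyz = as.vector(t(x@xyz)),
                   resno = x@resno, resid = x@resname, chain = x@chain,
                   elety = rep("CA", n), o = rep(1, n), b = b)
  if (any(x@charge != 0L) || !is.null(chargePath)) {
    if (is.null(chargePath)) chargePath <- paste0(path, ".charges.tsv")
    utils::write.table(
      data.frame(chain = x@chain, resno = x@resno, charge = x@charge),
      chargePath, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Export a 3N displacement/mode field for visualization
#'
#' Writes either NMD (normal mode wizard exchange format: a coordinates
#' line plus one mode line, loadable by external viewers) or a TSV with
#' one arrow row per residue (chain, resno, dx, dy, dz, magnitude).
#'
#' @param x a [CaStructure-class].
#' @param v 3N numeric vector (length must equal 3 * nNodes(x)).
#' @param path output path.
#' @param format "tsv" or "nmd".
#' @param name label used inside the NMD file.
#' @return invisibly, the path.
#' @export
writeDisplacementField <- function(x, v, path, format = c("tsv", "nmd"),
                                   name = "field") {
  stopifnot(is(x, "CaStructure"))
  format <- match.arg(format)
  n <- nNodes(x)
  if (length(v) != 3L * n)
    stop(sprintf("vector length %d != 3N = %d", length(v), 3L * n), call. = FALSE)
  if (format == "tsv") {
    m <- matrix(v, nrow = 3L)
    df <- data.frame(chain = x@chain, resno = x@resno,
                     dx = m[1L, ], dy = m[2L, ], dz = m[3L, ],
                     magnitude = vectorMagnitudes(v))
    utils::write.table(format(df, digits = 10), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  } else {
    num <- function(z) paste(format(z, digits = 10, trim = TRUE), collapse = " ")
    lines <- c(
      paste("nmwiz_load", basename(path)),
      paste("name", name),
      paste("resids", paste(x@resno, collapse = " ")),
      paste("chainids", paste(x@chain, collapse = " ")),
      paste("coordinates", num(as.vector(t(x@xyz)))),
      paste("mode 1 1.0", num(v))
    )
    writeLines(lines, path)
  }
  invisible(path)
}
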