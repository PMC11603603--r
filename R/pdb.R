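#' Read an all-atom structure and topology from a PDB file
#'
#' Parses standard PDB v3.3 columns via \pkg{bio3d}. Because PDB files
#' often lack CONECT records, bonds are inferred geometrically by
#' element-dependent distance cutoffs (see \code{\link{inferBonds}}) unless
#' an explicit bond list is supplied.
#'
#' @param file path to a PDB file.
#' @param bonds optional two-column matrix of 1-based bonds overriding
#'   inference.
#' @return list with elements \code{topology} (a \linkS4class{Topology})
#'   and \code{frame} (an \linkS4class{AllAtomFrame} with coordinates).
#' @export
readTopologyPDB <- function(file, bonds = NULL) {
  pdb <- bio3d::read.pdb(file)
  at <- pdb$atom
  el <- toupper(at$elesy)
  noEl <- is.na(el) | el == ""
  if (any(noEl)) # fall back on the first letter of the atom name
    el[noEl] <- substr(gsub("^[0-9]", "", toupper(at$elety[noEl])), 1, 1)
  x <- cbind(at$x, at$y, at$z)
  if (is.null(bonds)) bonds <- inferBonds(x, el)
  top <- topology(data.frame(element = el, resid = at$resno,
                             resname = at$resid, name = at$elety),
                  bonds)
  list(topology = top, frame = allAtomFrame(x))
}

#' Infer bonds from interatomic distances
#'
#' Element-dependent distance criteria: a hydrogen is bonded to its nearest
#' heavy atom when closer than \code{hCutoff}; heavy-atom pairs are bonded
#' below \code{heavyCutoff} (a longer \code{sCutoff} applies when either
#' atom is sulfur).
#'
#' @param coords N x 3 coordinate matrix (Angstrom).
#' @param elements length-N element symbols.
#' @param hCutoff hydrogen--heavy bond cutoff (Angstrom).
#' @param heavyCutoff heavy--heavy bond cutoff (Angstrom).
#' @param sCutoff cutoff when sulfur is involved (Angstrom).
#' @return two-column integer matrix of bonds.
#' @export
inferBonds <- function(coords, elements, hCutoff = 1.2,
                       heavyCutoff = 1.9, sCutoff = 2.2) {
  n <- nrow(coords)
  d <- as.matrix(stats::dist(coords))
  diag(d) <- Inf
  isH <- elements == "H"
  heavy <- which(!isH)
  bonds <- NULL
  for (h in which(isH)) {
    j <- heavy[which.min(d[h, heavy])]
    if (d[h, j] < hCutoff) bonds <- rbind(bonds, c(j, h))
  }
  if (length(heavy) > 1) {
    dh <- d[heavy, heavy, drop = FALSE]
    cut <- matrix(heavyCutoff, length(heavy), length(heavy))
    isS <- elements[heavy] == "S"
    cut[isS, ] <- sCutoff
    cut[, isS] <- sCutoff
    hit <- which(dh < cut & upper.tri(dh), arr.ind = TRUE)
    if (nrow(hit))
      bonds <- rbind(bonds, cbind(heavy[hit[, 1]], heavy[hit[, 2]]))
  }
  if (is.null(bonds)) matrix(integer(), 0, 2) else
    matrix(as.integer(bonds), ncol = 2)
}

#' Write a topology and coordinates to a PDB file
#'
#' @param top a \linkS4class{Topology}.
#' @param frame an \linkS4class{AllAtomFrame}.
#' @param file output path.
#' @export
writePDB <- function(top, frame, file) {
  a <- top@atoms
  bio3d::write.pdb(file = file, xyz = as.vector(t(coords(frame))),
                   resno = a$resid, resid = a$resname, elety = a$name,
                   elesy = a$element)
  invisible(file)
}
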