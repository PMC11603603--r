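# Heavy-atom templates for the 20 standard amino acids at standard (pH 7)
# protonation, mid-chain: atom name, element, number of bonded hydrogens,
# and the intra-residue heavy-heavy bond graph. Backbone atoms are added by
# the builder; side-chain protonation follows the usual conventions
# (LYS NH3+, ARG guanidinium, ASP/GLU carboxylate, HIS neutral N-epsilon
# tautomer, CYS thiol, MET thioether).

.sc <- function(names, elements, nH, bonds) {
  list(atoms = data.frame(name = names, element = elements, nH = nH),
       bonds = bonds)
}

.sidechains <- list(
  ALA = .sc("CB", "C", 3, NULL),
  ARG = .sc(c("CB", "CG", "CD", "NE", "CZ", "NH1", "NH2"),
            c("C", "C", "C", "N", "C", "N", "N"),
            c(2, 2, 2, 1, 0, 2, 2),
            rbind(c("CB", "CG"), c("CG", "CD"), c("CD", "NE"),
                  c("NE", "CZ"), c("CZ", "NH1"), c("CZ", "NH2"))),
  ASN = .sc(c("CB", "CG", "OD1", "ND2"), c("C", "C", "O", "N"),
            c(2, 0, 0, 2),
            rbind(c("CB", "CG"), c("CG", "OD1"), c("CG", "ND2"))),
  ASP = .sc(c("CB", "CG", "OD1", "OD2"), c("C", "C", "O", "O"),
            c(2, 0, 0, 0),
            rbind(c("CB", "CG"), c("CG", "OD1"), c("CG", "OD2"))),
  CYS = .sc(c("CB", "SG"), c("C", "S"), c(2, 1), rbind(c("CB", "SG"))),
  GLN = .sc(c("CB", "CG", "CD", "OE1", "NE2"), c("C", "C", "C", "O", "N"),
            c(2, 2, 0, 0, 2),
            rbind(c("CB", "CG"), c("CG", "CD"), c("CD", "OE1"),
                  c("CD", "NE2"))),
  GLU = .sc(c("CB", "CG", "CD", "OE1", "OE2"), c("C", "C", "C", "O", "O"),
            c(2, 2, 0, 0, 0),
            rbind(c("CB", "CG"), c("CG", "CD"), c("CD", "OE1"),
                  c("CD", "OE2"))),
  GLY = .sc(character(), character(), integer(), NULL),
  HIS = .sc(c("CB", "CG", "ND1", "CD2", "CE1", "NE2"),
            c("C", "C", "N", "C", "C", "N"), c(2, 0, 0, 1, 1, 1),
            rbind(c("CB", "CG"), c("CG", "ND1"), c("CG", "CD2"),
                  c("ND1", "CE1"), c("CD2", "NE2"), c("CE1", "NE2"))),
  ILE = .sc(c("CB", "CG1", "CG2", "CD1"), c("C", "C", "C", "C"),
            c(1, 2, 3, 3),
            rbind(c("CB", "CG1"), c("CB", "CG2"), c("CG1", "CD1"))),
  LEU = .sc(c("CB", "CG", "CD1", "CD2"), c("C", "C", "C", "C"),
            c(2, 1, 3, 3),
            rbind(c("CB", "CG"), c("CG", "CD1"), c("CG", "CD2"))),
  LYS = .sc(c("CB", "CG", "CD", "CE", "NZ"), c("C", "C", "C", "C", "N"),
            c(2, 2, 2, 2, 3),
            rbind(c("CB", "CG"), c("CG", "CD"), c("CD", "CE"),
                  c("CE", "NZ"))),
  MET = .sc(c("CB", "CG", "SD", "CE"), c("C", "C", "S", "C"),
            c(2, 2, 0, 3),
            rbind(c("CB", "CG"), c("CG", "SD"), c("SD", "CE"))),
  PHE = .sc(c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
            c("C", "C", "C", "C", "C", "C", "C"), c(2, 0, 1, 1, 1, 1, 1),
            rbind(c("CB", "CG"), c("CG", "CD1"), c("CG", "CD2"),
                  c("CD1", "CE1"), c("CD2", "CE2"), c("CE1", "CZ"),
                  c("CE2", "CZ"))),
  PRO = .sc(c("CB", "CG", "CD"), c("C", "C", "C"), c(2, 2, 2),
            rbind(c("CB", "CG"), c("CG", "CD"), c("CD", "N"))),
  SER = .sc(c("CB", "OG"), c("C", "O"), c(2, 1), rbind(c("CB", "OG"))),
  THR = .sc(c("CB", "OG1", "CG2"), c("C", "O", "C"), c(1, 1, 3),
            rbind(c("CB", "OG1"), c("CB", "CG2"))),
  TRP = .sc(c("CB", "CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2",
              "CZ3", "CH2"),
            c("C", "C", "C", "C", "N", "C", "C", "C", "C", "C"),
            c(2, 0, 1, 0, 1, 0, 1, 1, 1, 1),
            rbind(c("CB", "CG"), c("CG", "CD1"), c("CG", "CD2"),
                  c("CD1", "NE1"), c("NE1", "CE2"), c("CD2", "CE2"),
                  c("CD2", "CE3"), c("CE2", "CZ2"), c("CE3", "CZ3"),
                  c("CZ2", "CH2"), c("CZ3", "CH2"))),
  TYR = .sc(c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ", "OH"),
            c("C", "C", "C", "C", "C", "C", "C", "O"),
            c(2, 0, 1, 1, 1, 1, 0, 1),
            rbind(c("CB", "CG"), c("CG", "CD1"), c("CG", "CD2"),
                  c("CD1", "CE1"), c("CD2", "CE2"), c("CE1", "CZ"),
                  c("CE2", "CZ"), c("CZ", "OH"))),
  VAL = .sc(c("CB", "CG1", "CG2"), c("C", "C", "C"), c(1, 3, 3),
            rbind(c("CB", "CG1"), c("CB", "CG2")))
)

.aa1to3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
             Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
             L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
             S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

#' Names of the 20 standard amino acids
#'
#' @return character vector of three-letter residue codes.
#' @export
standardResidues <- function() names(.sidechains)

# Heavy-atom table (name, element, nH) for one residue incl. backbone.
.residueHeavy <- function(resname) {
  sc <- .sidechains[[resname]]
  if (is.null(sc)) stop("unknown residue: ", resname)
  bb <- data.frame(name = c("N", "CA", "C", "O"),
                   element = c("N", "C", "C", "O"),
                   nH = c(if (resname == "PRO") 0L else 1L,
                          if (resname == "GLY") 2L else 1L, 0L, 0L))
  rbind(bb, sc$atoms)
}

# Heavy-heavy bond name pairs for one residue (intra-residue).
.residueBonds <- function(resname) {
  sc <- .sidechains[[resname]]
  b <- rbind(c("N", "CA"), c("CA", "C"), c("C", "O"))
  if (nrow(sc$atoms)) b <- rbind(b, c("CA", "CB"))
  if (!is.null(sc$bonds)) b <- rbind(b, sc$bonds)
  b
}

# Assemble a Topology from heavy-atom tables: attaches nH hydrogens to each
# heavy atom and resolves named bonds to indices.
.assembleTopology <- function(heavy, namedBonds) {
  nh <- nrow(heavy)
  atoms <- data.frame(element = heavy$element, resid = heavy$resid,
                      resname = heavy$resname, name = heavy$name)
  key <- paste(heavy$resid, heavy$name)
  idx <- stats::setNames(seq_len(nh), key)
  bonds <- cbind(idx[paste(namedBonds[, 1], namedBonds[, 2])],
                 idx[paste(namedBonds[, 3], namedBonds[, 4])])
  if (anyNA(bonds)) stop("unresolved bond name in residue template")
  hBonds <- NULL
  for (i in seq_len(nh)) {
    k <- heavy$nH[i]
    if (k > 0) {
      hIdx <- nrow(atoms) + seq_len(k)
      atoms <- rbind(atoms, data.frame(
        element = rep("H", k), resid = rep(heavy$resid[i], k),
        resname = rep(heavy$resname[i], k),
        name = paste0("H", heavy$name[i], seq_len(k))))
      hBonds <- rbind(hBonds, cbind(rep(i, k), hIdx))
    }
  }
  topology(atoms, rbind(bonds, hBonds))
}

#' Topology of a single standard residue
#'
#' Builds the all-atom topology (heavy atoms plus explicit hydrogens, with
#' bonds) of one residue in its mid-chain form: the backbone nitrogen
#' carries one hydrogen (none for proline) and no OXT is added. Side-chain
#' protonation is standard at pH 7.
#'
#' @param resname three-letter residue code.
#' @return a \linkS4class{Topology}.
#' @export
residueTopology <- function(resname) {
  resname <- toupper(resname)
  heavy <- .residueHeavy(resname)
  heavy$resid <- 1L
  heavy$resname <- resname
  b <- .residueBonds(resname)
  namedBonds <- cbind(1L, b[, 1], 1L, b[, 2])
  .assembleTopology(heavy, namedBonds)
}

#' Build a peptide topology from a sequence
#'
#' Assembles the all-atom topology of a linear peptide, with explicit
#' hydrogens, from the package's residue templates. With \code{capped =
#' TRUE} the chain is terminated with acetyl (ACE) and N-methylamide (NME)
#' groups; otherwise the termini stay in their mid-chain form and a terminal
#' carboxyl OXT oxygen is appended.
#'
#' @param sequence one-letter string (e.g. \code{"YYDPETGTWY"}) or a
#'   character vector of three-letter codes.
#' @param capped logical; terminate with ACE/NME caps.
#' @return a \linkS4class{Topology}.
#' @export
buildPeptideTopology <- function(sequence, capped = FALSE) {
  if (length(sequence) == 1 && !sequence %in% names(.sidechains)) {
    res <- .aa1to3[strsplit(sequence, "")[[1]]]
    if (anyNA(res)) stop("unknown one-letter code in sequence")
  } else res <- toupper(sequence)
  heavy <- NULL
  namedBonds <- NULL
  rid <- 0L
  addRes <- function(tbl, bonds, resname) {
    rid <<- rid + 1L
    tbl$resid <- rid
    tbl$resname <- resname
    heavy <<- rbind(heavy, tbl)
    if (!is.null(bonds))
      namedBonds <<- rbind(namedBonds, cbind(rid, bonds[, 1], rid,
                                             bonds[, 2]))
  }
  if (capped)
    addRes(data.frame(name = c("CH3", "C", "O"),
                      element = c("C", "C", "O"), nH = c(3L, 0L, 0L)),
           rbind(c("CH3", "C"), c("C", "O")), "ACE")
  for (r in res) addRes(.residueHeavy(r), .residueBonds(r), r)
  if (capped)
    addRes(data.frame(name = c("N", "CH3"), element = c("N", "C"),
                      nH = c(1L, 3L)), rbind(c("N", "CH3")), "NME")
  else {
    heavy <- rbind(heavy, data.frame(name = "OXT", element = "O", nH = 0L,
                                     resid = rid, resname = res[length(res)]))
  }
  # peptide bonds C(i) - N(i+1)
  for (i in seq_len(rid - 1L))
    namedBonds <- rbind(namedBonds, cbind(i, "C", i + 1L, "N"))
  if (!capped)
    namedBonds <- rbind(namedBonds, cbind(rid, "C", rid, "OXT"))
  .assembleTopology(heavy, namedBonds)
}
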