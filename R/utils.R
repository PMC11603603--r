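# Package-wide unit system: Angstrom, kcal/mol, kcal/mol/A, a.m.u., fs.
# Velocities are A/fs; 1 kcal/mol = .accFactor amu A^2/fs^2.
.kB <- 1.987204259e-3        # kcal/(mol K)
.accFactor <- 4.184e-4       # (kcal/mol/A) / amu -> A/fs^2

#' Boltzmann constant in package units
#'
#' @return k_B in kcal/(mol K).
#' @export
boltzmannConstant <- function() .kB

.elementMasses <- c(C = 12.011, N = 14.007, O = 15.999, S = 32.06,
                    H = 1.008)

#' Construct a topology
#'
#' @param atoms data.frame with columns \code{element}, \code{resid},
#'   \code{resname}, \code{name} (missing metadata columns are filled with
#'   defaults).
#' @param bonds two-column matrix of 1-based atom index pairs.
#' @return a \linkS4class{Topology}.
#' @export
topology <- function(atoms, bonds = matrix(integer(), 0, 2)) {
  if (is.character(atoms))
    atoms <- data.frame(element = atoms)
  if (is.null(atoms$resid)) atoms$resid <- 1L
  if (is.null(atoms$resname)) atoms$resname <- "UNK"
  if (is.null(atoms$name)) atoms$name <- atoms$element
  bonds <- matrix(as.integer(bonds), ncol = 2)
  new("Topology", atoms = atoms, bonds = bonds)
}

#' Construct an all-atom frame
#'
#' @param coords N x 3 coordinate matrix (Angstrom).
#' @param forces optional N x 3 force matrix (kcal/mol/Angstrom).
#' @return an \linkS4class{AllAtomFrame}.
#' @export
allAtomFrame <- function(coords, forces = NULL) {
  new("AllAtomFrame", coords = as.matrix(coords),
      forces = if (is.null(forces)) NULL else as.matrix(forces))
}

#' Construct a CG frame
#'
#' @param coords n x 3 bead coordinates (Angstrom).
#' @param beadTypes length-n integer bead types.
#' @param forces optional n x 3 aggregated forces (kcal/mol/Angstrom).
#' @return a \linkS4class{CGFrame}.
#' @export
cgFrame <- function(coords, beadTypes, forces = NULL) {
  new("CGFrame", coords = as.matrix(coords),
      forces = if (is.null(forces)) NULL else as.matrix(forces),
      beadTypes = as.integer(beadTypes))
}

#' Construct a CG dataset
#'
#' @param frames list of \linkS4class{CGFrame} objects.
#' @param domain per-frame domain id (recycled).
#' @param temperature per-frame temperature in K (recycled).
#' @return a \linkS4class{CGDataset}.
#' @export
cgDataset <- function(frames, domain = "toy", temperature = NA_real_) {
  n <- length(frames)
  new("CGDataset", frames = frames,
      domain = rep_len(as.character(domain), n),
      temperature = rep_len(as.numeric(temperature), n))
}

#' Subset a CG dataset
#'
#' @param x a \linkS4class{CGDataset}.
#' @param i frame indices.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "CGDataset", function(x, i, j, ..., drop = FALSE) {
  new("CGDataset", frames = x@frames[i], domain = x@domain[i],
      temperature = x@temperature[i])
})

# Random orthogonal matrix in O(3) (Haar via QR); may include reflections.
randomOrthogonal <- function(properOnly = FALSE) {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_) %*% diag(sign(diag(qr.R(qr_))))
  if (properOnly && det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# Kabsch optimal-superposition RMSD between two n x 3 coordinate sets.
kabschRMSD <- function(a, b) {
  a <- sweep(a, 2, colMeans(a))
  b <- sweep(b, 2, colMeans(b))
  s <- svd(crossprod(b, a))
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  sqrt(mean(rowSums((a - b %*% R)^2)))
}
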