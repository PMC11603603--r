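#' @import methods
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))
setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' All-atom molecular topology
#'
#' Holds the fine-grained system: one row per atom (element symbol, residue
#' index, residue name, atom name) plus a bond list. This is the basis for
#' the no-hydrogen coarse-graining map: each hydrogen must be bonded to
#' exactly one heavy atom, and protein inputs are restricted to the elements
#' C, N, O, S and H.
#'
#' @slot atoms data.frame with columns \code{element}, \code{resid},
#'   \code{resname}, \code{name}.
#' @slot bonds two-column integer matrix of 1-based atom indices.
#' @export
setClass("Topology",
  representation(atoms = "data.frame", bonds = "matrix"))

setValidity("Topology", function(object) {
  a <- object@atoms
  msg <- character()
  need <- c("element", "resid", "resname", "name")
  if (!all(need %in% names(a)))
    return(paste("atoms must have columns", paste(need, collapse = ", ")))
  bad <- setdiff(unique(a$element), c("C", "N", "O", "S", "H"))
  if (length(bad))
    msg <- c(msg, paste("unsupported element(s):", paste(bad, collapse = ", ")))
  b <- object@bonds
  if (ncol(b) != 2) msg <- c(msg, "bonds must have two columns")
  else if (nrow(b) && (min(b) < 1 || max(b) > nrow(a)))
    msg <- c(msg, "bond indices out of range")
  if (length(msg)) msg else TRUE
})

#' Bead-type table
#'
#' Maps each (element, bonded-hydrogen count) class realized by a residue set
#' to a contiguous integer embedding id, and records element masses in a.m.u.
#' For the 20 standard amino acids at standard protonation exactly 12 classes
#' are realized.
#'
#' @slot entries data.frame with columns \code{element}, \code{nH}, \code{id}.
#' @slot elementMasses named numeric vector of element masses (a.m.u.).
#' @export
setClass("BeadTypeTable",
  representation(entries = "data.frame", elementMasses = "numeric"))

setValidity("BeadTypeTable", function(object) {
  e <- object@entries
  if (!all(c("element", "nH", "id") %in% names(e)))
    return("entries must have columns element, nH, id")
  if (nrow(e)) {
    if (!identical(sort(e$id), seq_len(nrow(e))))
      return("ids must be contiguous from 1")
    if (anyDuplicated(paste(e$element, e$nH)))
      return("duplicate (element, nH) entry")
  }
  TRUE
})

#' No-hydrogen coarse-graining map
#'
#' The linear selection operator from an all-atom system to its heavy-atom
#' beads, together with each bead's bonded-hydrogen set, its integer
#' embedding type, and its aggregated mass (heavy atom plus bonded
#' hydrogens).
#'
#' @slot heavyIndices strictly increasing 1-based all-atom indices retained
#'   as beads.
#' @slot hydrogenSets per-bead list of all-atom hydrogen indices; pairwise
#'   disjoint and jointly covering all hydrogens.
#' @slot beadTypes per-bead integer embedding.
#' @slot beadMasses per-bead mass in a.m.u.
#' @export
setClass("CGMap",
  representation(heavyIndices = "integer", hydrogenSets = "list",
                 beadTypes = "integer", beadMasses = "numeric"))

setValidity("CGMap", function(object) {
  n <- length(object@heavyIndices)
  if (n > 1 && any(diff(object@heavyIndices) <= 0))
    return("heavyIndices must be strictly increasing")
  if (length(object@hydrogenSets) != n || length(object@beadTypes) != n ||
      length(object@beadMasses) != n)
    return("per-bead slots must have one entry per heavy atom")
  hs <- unlist(object@hydrogenSets)
  if (anyDuplicated(hs)) return("hydrogen sets must be pairwise disjoint")
  if (any(object@beadMasses <= 0)) return("bead masses must be positive")
  TRUE
})

#' All-atom frame
#'
#' Coordinates (and optionally forces) for one conformation of an all-atom
#' system. Units: Angstrom and kcal/mol/Angstrom.
#'
#' @slot coords N x 3 numeric matrix.
#' @slot forces N x 3 numeric matrix or NULL.
#' @export
setClass("AllAtomFrame",
  representation(coords = "matrix", forces = "matrixOrNULL"))

validFrame <- function(object) {
  if (ncol(object@coords) != 3) return("coords must be N x 3")
  if (!all(is.finite(object@coords))) return("coords must be finite")
  if (!is.null(object@forces)) {
    if (!identical(dim(object@forces), dim(object@coords)))
      return("forces must match coords in shape")
    if (!all(is.finite(object@forces))) return("forces must be finite")
  }
  TRUE
}
setValidity("AllAtomFrame", validFrame)

#' Coarse-grained frame
#'
#' Bead coordinates, optional aggregated forces, and per-bead integer types
#' for one CG conformation.
#'
#' @slot coords n x 3 numeric matrix (Angstrom).
#' @slot forces n x 3 numeric matrix (kcal/mol/Angstrom) or NULL.
#' @slot beadTypes length-n integer vector.
#' @export
setClass("CGFrame",
  representation(coords = "matrix", forces = "matrixOrNULL",
                 beadTypes = "integer"))

setValidity("CGFrame", function(object) {
  v <- validFrame(object)
  if (!isTRUE(v)) return(v)
  if (length(object@beadTypes) != nrow(object@coords))
    return("beadTypes must have one entry per bead")
  TRUE
})

#' Coarse-grained coordinate--force dataset
#'
#' A flat list of CG frames with per-frame provenance (domain id,
#' temperature), ready for force-matching training.
#'
#' @slot frames list of \code{CGFrame}.
#' @slot domain character vector, one id per frame.
#' @slot temperature numeric vector (K), one value per frame.
#' @export
setClass("CGDataset",
  representation(frames = "list", domain = "character",
                 temperature = "numeric"))

setValidity("CGDataset", function(object) {
  n <- length(object@frames)
  if (length(object@domain) != n || length(object@temperature) != n)
    return("domain and temperature must have one entry per frame")
  if (n && !all(vapply(object@frames, is, logical(1), "CGFrame")))
    return("frames must be CGFrame objects")
  TRUE
})

#' Invariant radial-basis pair potential
#'
#' A coarse-grained potential that is a linear combination of Gaussian
#' radial basis functions of interbead distance, modulated by a smooth
#' cosine cutoff envelope, with one coefficient vector per unordered pair of
#' bead types. The energy is invariant under rotations, reflections and
#' translations by construction, and the forces (its exact negative
#' gradient) are equivariant. Because the model is linear in its
#' coefficients, force matching reduces to a quadratic problem with
#' analytically available sufficient statistics.
#'
#' @slot nTypes number of bead types the potential accepts.
#' @slot centers radial basis centers (Angstrom).
#' @slot width shared Gaussian width (Angstrom).
#' @slot cutoff receptive field (Angstrom); beads farther apart do not
#'   interact.
#' @slot coef coefficient matrix, one row per unordered type pair, one
#'   column per basis function.
#' @export
setClass("RadialPairPotential",
  representation(nTypes = "integer", centers = "numeric", width = "numeric",
                 cutoff = "numeric", coef = "matrix"))

setValidity("RadialPairPotential", function(object) {
  P <- object@nTypes * (object@nTypes + 1L) / 2L
  if (nrow(object@coef) != P)
    return("coef must have one row per unordered type pair")
  if (ncol(object@coef) != length(object@centers))
    return("coef must have one column per basis center")
  if (object@cutoff <= 0 || object@width <= 0)
    return("cutoff and width must be positive")
  TRUE
})

#' Closed-form toy force field
#'
#' An analytic all-atom force field over a toy topology: harmonic bonds,
#' optional double-well bonds, harmonic angles, Lennard-Jones pairs and
#' harmonic position tethers. Used by the synthetic-systems generator as
#' the known ground truth from which coordinate--force training data are
#' sampled.
#'
#' @slot terms list of term tables passed to the compiled evaluator.
#' @export
setClass("ToyForceField", representation(terms = "list"))

#' Langevin simulation state
#'
#' @slot coords n x 3 bead coordinates (Angstrom).
#' @slot velocities n x 3 bead velocities (Angstrom/fs).
#' @slot masses per-bead masses (a.m.u.).
#' @slot beadTypes per-bead integer types (used by CG potentials).
#' @slot step integer step counter.
#' @export
setClass("SimState",
  representation(coords = "matrix", velocities = "matrix",
                 masses = "numeric", beadTypes = "integer",
                 step = "integer"))

setValidity("SimState", function(object) {
  if (!identical(dim(object@coords), dim(object@velocities)))
    return("coords and velocities must have the same shape")
  if (length(object@masses) != nrow(object@coords))
    return("one mass per bead required")
  if (any(object@masses <= 0)) return("masses must be positive")
  if (!all(is.finite(object@coords)) || !all(is.finite(object@velocities)))
    return("state must be finite")
  TRUE
})

#' Simulation trajectory
#'
#' Frames saved by the Langevin engine at a fixed output stride, with
#' per-frame potential energies and the configuration used to produce them.
#'
#' @slot coords F x n x 3 array (Angstrom).
#' @slot velocities F x n x 3 array or NULL.
#' @slot energies per-frame potential energy (kcal/mol).
#' @slot times per-frame simulation time (fs).
#' @slot config list of simulation settings.
#' @export
setClass("Trajectory",
  representation(coords = "array", velocities = "ANY", energies = "numeric",
                 times = "numeric", config = "list"))

#' TICA model
#'
#' Time-lagged independent component analysis artifacts: feature means,
#' instantaneous and lagged covariance matrices, and the generalized
#' eigenvectors (projection basis) sorted by decreasing eigenvalue.
#'
#' @slot mean feature means.
#' @slot c0 instantaneous covariance.
#' @slot ctau symmetrized lagged covariance.
#' @slot eigenvalues real eigenvalues, sorted descending.
#' @slot vectors projection vectors (columns).
#' @slot lag lag time in frames.
#' @export
setClass("TICAModel",
  representation(mean = "numeric", c0 = "matrix", ctau = "matrix",
                 eigenvalues = "numeric", vectors = "matrix",
                 lag = "integer"))

#' Markov state model estimate
#'
#' @slot transition row-stochastic transition matrix over the active state
#'   set.
#' @slot lag lag time in frames.
#' @slot stationary stationary distribution (left fixed point).
#' @slot states original microstate labels of the active (largest connected)
#'   set.
#' @slot counts transition count matrix at the lag.
#' @slot macrostates optional per-state macrostate assignment.
#' @export
setClass("MSMResult",
  representation(transition = "matrix", lag = "integer",
                 stationary = "numeric", states = "integer",
                 counts = "matrix", macrostates = "integer"))

setValidity("MSMResult", function(object) {
  T_ <- object@transition
  if (nrow(T_) != ncol(T_)) return("transition matrix must be square")
  if (any(T_ < -1e-12)) return("transition probabilities must be >= 0")
  if (nrow(T_) && max(abs(rowSums(T_) - 1)) > 1e-8)
    return("transition matrix rows must sum to 1")
  TRUE
})

#' Two-dimensional free-energy surface
#'
#' Free energy per bin of a 2-D grid over projected coordinates, in units of
#' k_B T, min-shifted to zero; empty bins are NA.
#'
#' @slot xEdges,yEdges bin edges.
#' @slot energy matrix of free energies (k_B T).
#' @slot temperature reference temperature (K).
#' @export
setClass("FreeEnergySurface",
  representation(xEdges = "numeric", yEdges = "numeric", energy = "matrix",
                 temperature = "numeric"))

#' Analytic coarse-grained potential of mean force
#'
#' @slot grid reaction-coordinate grid (Angstrom).
#' @slot energy free energy on the grid (kcal/mol), min-shifted to zero.
#' @slot description closed-form description.
#' @export
setClass("AnalyticPMF",
  representation(grid = "numeric", energy = "numeric",
                 description = "character"))
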