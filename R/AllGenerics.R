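#' @rdname accessors
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))
#' @rdname accessors
#' @export
setGeneric("nBeads", function(x) standardGeneric("nBeads"))
#' @rdname accessors
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))
#' @rdname accessors
#' @export
setGeneric("forces", function(x) standardGeneric("forces"))
#' @rdname accessors
#' @export
setGeneric("beadTypes", function(x) standardGeneric("beadTypes"))
#' @rdname accessors
#' @export
setGeneric("beadMasses", function(x) standardGeneric("beadMasses"))
#' @rdname accessors
#' @export
setGeneric("heavyIndices", function(x) standardGeneric("heavyIndices"))
#' @rdname accessors
#' @export
setGeneric("hydrogenSets", function(x) standardGeneric("hydrogenSets"))
#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' Potential energy of a configuration
#'
#' @param object a potential (e.g. \linkS4class{RadialPairPotential} or
#'   \linkS4class{ToyForceField}).
#' @param coords n x 3 coordinate matrix (Angstrom) or a
#'   \linkS4class{CGFrame}.
#' @param ... method-specific arguments.
#' @return scalar energy in kcal/mol.
#' @export
setGeneric("potentialEnergy",
           function(object, coords, ...) standardGeneric("potentialEnergy"))

#' Forces of a potential
#'
#' The exact negative gradient of \code{\link{potentialEnergy}} with respect
#' to the coordinates.
#'
#' @inheritParams potentialEnergy
#' @return n x 3 force matrix in kcal/mol/Angstrom.
#' @export
setGeneric("potentialForces",
           function(object, coords, ...) standardGeneric("potentialForces"))

#' Accessors for nohcg objects
#'
#' \code{nAtoms}, \code{nBeads}, \code{coords}, \code{forces},
#' \code{beadTypes}, \code{beadMasses}, \code{heavyIndices},
#' \code{hydrogenSets} and \code{nFrames} extract the corresponding
#' components of topologies, maps, frames, datasets and trajectories.
#'
#' @param x the object.
#' @name accessors
NULL

setMethod("nAtoms", "Topology", function(x) nrow(x@atoms))
setMethod("nBeads", "CGMap", function(x) length(x@heavyIndices))
setMethod("nBeads", "CGFrame", function(x) nrow(x@coords))
setMethod("coords", "AllAtomFrame", function(x) x@coords)
setMethod("coords", "CGFrame", function(x) x@coords)
setMethod("coords", "Trajectory", function(x) x@coords)
setMethod("forces", "AllAtomFrame", function(x) x@forces)
setMethod("forces", "CGFrame", function(x) x@forces)
setMethod("beadTypes", "CGMap", function(x) x@beadTypes)
setMethod("beadTypes", "CGFrame", function(x) x@beadTypes)
setMethod("beadMasses", "CGMap", function(x) x@beadMasses)
setMethod("heavyIndices", "CGMap", function(x) x@heavyIndices)
setMethod("hydrogenSets", "CGMap", function(x) x@hydrogenSets)
setMethod("nFrames", "CGDataset", function(x) length(x@frames))
setMethod("nFrames", "Trajectory", function(x) dim(x@coords)[1])

setMethod("show", "Topology", function(object) {
  a <- object@atoms
  cat("Topology:", nrow(a), "atoms (", sum(a$element != "H"), "heavy,",
      sum(a$element == "H"), "H ),", nrow(object@bonds), "bonds,",
      length(unique(a$resid)), "residues\n")
})

setMethod("show", "CGMap", function(object) {
  cat("CGMap:", nBeads(object), "noh beads,",
      length(unlist(object@hydrogenSets)), "hydrogens absorbed,",
      length(unique(object@beadTypes)), "bead types\n")
})

setMethod("show", "BeadTypeTable", function(object) {
  e <- object@entries
  cat("BeadTypeTable:", nrow(e), "(element, nH) classes\n")
  if (nrow(e))
    cat(" ", paste0(e$element, e$nH, "=", e$id, collapse = " "), "\n")
})

setMethod("show", "CGFrame", function(object) {
  cat("CGFrame:", nBeads(object), "beads",
      if (is.null(object@forces)) "(coordinates only)" else
        "(coordinates + forces)", "\n")
})

setMethod("show", "CGDataset", function(object) {
  cat("CGDataset:", nFrames(object), "frames,",
      length(unique(object@domain)), "domain(s), temperatures:",
      paste(sort(unique(object@temperature)), collapse = "/"), "K\n")
})

setMethod("show", "RadialPairPotential", function(object) {
  cat("RadialPairPotential:", object@nTypes, "bead types,",
      length(object@centers), "radial bases, cutoff",
      object@cutoff, "A\n")
})

setMethod("show", "Trajectory", function(object) {
  d <- dim(object@coords)
  cat("Trajectory:", d[1], "frames x", d[2], "beads;",
      "dt =", object@config$timestep, "fs, output stride =",
      object@config$outputStride, "\n")
})

setMethod("show", "TICAModel", function(object) {
  cat("TICAModel: lag", object@lag, "frames;",
      length(object@eigenvalues), "components; leading eigenvalues:",
      paste(signif(utils::head(object@eigenvalues, 4), 3), collapse = ", "),
      "\n")
})

setMethod("show", "MSMResult", function(object) {
  cat("MSMResult:", nrow(object@transition), "states, lag",
      object@lag, "frames\n")
})

setMethod("show", "FreeEnergySurface", function(object) {
  cat("FreeEnergySurface:", length(object@xEdges) - 1, "x",
      length(object@yEdges) - 1, "grid,",
      sum(!is.na(object@energy)), "populated bins, T =",
      object@temperature, "K\n")
})
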