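#' Enumerate bead-type classes from residue topologies
#'
#' Scans a set of residue topologies and collects every distinct
#' (element, bonded-hydrogen count) pair realized by their heavy atoms.
#' Ids are assigned deterministically: entries are sorted by element and
#' then by hydrogen count, and numbered contiguously from 1. For the 20
#' standard amino acids at standard protonation exactly 12 classes are
#' realized (C0--C3, N0--N3, O0, O1, S0, S1).
#'
#' @param residues list of \linkS4class{Topology} objects (e.g. from
#'   \code{\link{residueTopology}}).
#' @return a \linkS4class{BeadTypeTable}.
#' @examples
#' tab <- enumerateBeadTypes(lapply(standardResidues(), residueTopology))
#' nrow(tab@entries)  # 12
#' @export
enumerateBeadTypes <- function(residues) {
  pairs <- unique(do.call(rbind, lapply(residues, function(top) {
    counts <- .hydrogenCounts(top)
    heavy <- top@atoms$element != "H"
    data.frame(element = top@atoms$element[heavy], nH = counts[heavy])
  })))
  if (is.null(pairs))
    pairs <- data.frame(element = character(), nH = integer())
  pairs <- pairs[order(pairs$element, pairs$nH), , drop = FALSE]
  pairs$id <- seq_len(nrow(pairs))
  rownames(pairs) <- NULL
  new("BeadTypeTable", entries = pairs, elementMasses = .elementMasses)
}

# bonded-hydrogen count per atom; errors on unbonded or multiply-bonded H
.hydrogenCounts <- function(top) {
  el <- top@atoms$element
  n <- length(el)
  counts <- integer(n)
  hPartner <- integer(n) # per-hydrogen heavy partner count
  b <- top@bonds
  for (k in seq_len(nrow(b))) {
    i <- b[k, 1]; j <- b[k, 2]
    if (el[i] == "H" && el[j] != "H") {
      counts[j] <- counts[j] + 1L; hPartner[i] <- hPartner[i] + 1L
    } else if (el[j] == "H" && el[i] != "H") {
      counts[i] <- counts[i] + 1L; hPartner[j] <- hPartner[j] + 1L
    } else if (el[i] == "H" && el[j] == "H")
      stop("hydrogen-hydrogen bond between atoms ", i, " and ", j)
  }
  bad <- which(el == "H" & hPartner != 1L)
  if (length(bad))
    stop("hydrogen atom(s) not bonded to exactly one heavy atom: ",
         paste(bad, collapse = ", "))
  counts
}

#' Bead-type table for the 20 standard amino acids
#'
#' The canonical 12-class embedding table obtained by enumerating the
#' standard residues at standard protonation.
#'
#' @return a \linkS4class{BeadTypeTable} with 12 entries.
#' @export
standardBeadTypeTable <- function() {
  enumerateBeadTypes(lapply(standardResidues(), residueTopology))
}

#' Look up a bead-type id
#'
#' @param table a \linkS4class{BeadTypeTable}.
#' @param element element symbol(s).
#' @param nH bonded-hydrogen count(s).
#' @param strict if TRUE, unknown (element, nH) pairs raise an error; if
#'   FALSE they extend the lookup result with NA.
#' @return integer id(s).
#' @export
beadTypeId <- function(table, element, nH, strict = TRUE) {
  key <- paste(element, nH)
  tabKey <- paste(table@entries$element, table@entries$nH)
  id <- table@entries$id[match(key, tabKey)]
  if (strict && anyNA(id)) {
    miss <- unique(key[is.na(id)])
    stop("bead type(s) not in table: ", paste0("(", miss, ")",
                                               collapse = ", "))
  }
  id
}

#' Build the no-hydrogen coarse-graining map
#'
#' Constructs the noh map for an all-atom topology: one bead per heavy
#' atom, in ascending all-atom order; each bead records the set of
#' hydrogens bonded to its heavy atom, its (element, nH) embedding type
#' from \code{table}, and its aggregated mass (element mass plus bonded
#' hydrogen masses).
#'
#' With \code{strict = TRUE}, (element, nH) pairs absent from the table
#' (e.g. unusual terminal or protonation variants when using the canonical
#' 12-entry table) raise a typing error naming the pair; with
#' \code{strict = FALSE} the table is extended on the fly.
#'
#' @param top a \linkS4class{Topology}; every hydrogen must be bonded to
#'   exactly one heavy atom.
#' @param table a \linkS4class{BeadTypeTable}; defaults to the canonical
#'   12-class table.
#' @param strict reject (element, nH) pairs absent from \code{table}.
#' @return a \linkS4class{CGMap}.
#' @export
buildNohMap <- function(top, table = standardBeadTypeTable(),
                        strict = TRUE) {
  stopifnot(is(top, "Topology"))
  validObject(top)
  el <- top@atoms$element
  counts <- .hydrogenCounts(top)
  heavy <- which(el != "H")
  types <- beadTypeId(table, el[heavy], counts[heavy], strict = strict)
  if (anyNA(types)) { # non-strict: extend with new contiguous ids
    extra <- unique(data.frame(element = el[heavy], nH = counts[heavy])[
      is.na(types), , drop = FALSE])
    extra$id <- nrow(table@entries) + seq_len(nrow(extra))
    table@entries <- rbind(table@entries, extra)
    types <- beadTypeId(table, el[heavy], counts[heavy])
  }
  hSets <- rep(list(integer()), length(heavy))
  beadOf <- match(seq_along(el), heavy) # all-atom index -> bead index
  b <- top@bonds
  for (k in seq_len(nrow(b))) {
    i <- b[k, 1]; j <- b[k, 2]
    if (el[i] == "H" && el[j] != "H")
      hSets[[beadOf[j]]] <- c(hSets[[beadOf[j]]], i)
    else if (el[j] == "H" && el[i] != "H")
      hSets[[beadOf[i]]] <- c(hSets[[beadOf[i]]], j)
  }
  masses <- .elementMasses[el[heavy]] +
    counts[heavy] * .elementMasses[["H"]]
  new("CGMap", heavyIndices = as.integer(heavy), hydrogenSets = hSets,
      beadTypes = as.integer(types), beadMasses = unname(masses))
}

#' Map all-atom coordinates to CG coordinates
#'
#' The noh map is a pure selection: bead coordinates are exactly the
#' heavy-atom coordinates, in the order of \code{heavyIndices(map)}.
#'
#' @param frame an \linkS4class{AllAtomFrame} matching the topology used to
#'   build \code{map}.
#' @param map a \linkS4class{CGMap}.
#' @return a \linkS4class{CGFrame} (without forces).
#' @export
mapCoordinates <- function(frame, map) {
  x <- coords(frame)
  nTot <- length(map@heavyIndices) + length(unlist(map@hydrogenSets))
  if (nrow(x) != nTot)
    stop("frame has ", nrow(x), " atoms but the map expects ", nTot)
  cgFrame(x[map@heavyIndices, , drop = FALSE], map@beadTypes)
}

#' Aggregate all-atom forces onto CG beads
#'
#' Basic force aggregation: the force on bead i is the force on its heavy
#' atom plus the sum of forces on the hydrogens bonded to it. The total
#' force is conserved exactly: the bead forces sum componentwise to the sum
#' of all atomic forces.
#'
#' @inheritParams mapCoordinates
#' @return a \linkS4class{CGFrame} with coordinates and aggregated forces.
#' @export
aggregateForces <- function(frame, map) {
  f <- forces(frame)
  if (is.null(f)) stop("frame has no forces to aggregate")
  cg <- mapCoordinates(frame, map)
  F_ <- f[map@heavyIndices, , drop = FALSE]
  for (i in seq_along(map@hydrogenSets)) {
    hs <- map@hydrogenSets[[i]]
    if (length(hs))
      F_[i, ] <- F_[i, ] + colSums(f[hs, , drop = FALSE])
  }
  cgFrame(coords(cg), map@beadTypes, F_)
}

#' Aggregate forces across a stack of frames
#'
#' Vectorized convenience for applying \code{\link{aggregateForces}} to an
#' F x N x 3 coordinate/force array pair.
#'
#' @param coordArray,forceArray F x N x 3 arrays.
#' @param map a \linkS4class{CGMap}.
#' @return list with elements \code{coords} and \code{forces}
#'   (F x n x 3 arrays) and \code{beadTypes}.
#' @export
aggregateForcesArray <- function(coordArray, forceArray, map) {
  hv <- map@heavyIndices
  Fcg <- forceArray[, hv, , drop = FALSE]
  for (i in seq_along(map@hydrogenSets)) {
    hs <- map@hydrogenSets[[i]]
    for (h in hs) Fcg[, i, ] <- Fcg[, i, ] + forceArray[, h, ]
  }
  list(coords = coordArray[, hv, , drop = FALSE], forces = Fcg,
       beadTypes = map@beadTypes)
}
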