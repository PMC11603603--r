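#' Specify a toy all-atom molecule
#'
#' Defines a chain of heavy sites, each carrying a fixed number of
#' explicitly bonded hydrogens, governed by a closed-form force field:
#' harmonic bonds, optional harmonic H-X-H angles, optional Lennard-Jones
#' interactions between distant heavy sites, an optional double-well bond
#' replacing the first heavy-heavy harmonic bond, and optional harmonic
#' position tethers. Hydrogens are light satellites on stiff bonds, so
#' their forces aggregate onto the parent bead with exact internal
#' cancellation and the aggregated bead force is a clean estimator of the
#' coarse-grained mean force.
#'
#' @param nHeavy number of heavy sites.
#' @param hydrogens bonded-hydrogen count per site (recycled).
#' @param element heavy-site element symbol.
#' @param bondK,bondR0 heavy-heavy harmonic bond constant
#'   (kcal/mol/A^2) and rest length (A).
#' @param hBondK,hBondR0 hydrogen bond constant and rest length.
#' @param angleK,angleTheta0 H-X-H harmonic angle constant
#'   (kcal/mol/rad^2; 0 disables) and rest angle (rad).
#' @param ljEpsilon,ljSigma,ljMinSep Lennard-Jones parameters between
#'   heavy sites at least \code{ljMinSep} apart along the chain
#'   (\code{ljEpsilon = 0} disables).
#' @param dwell optional list \code{(h, w, r0, tilt)} putting a double-well
#'   potential \eqn{h (u^2 - 1)^2 + tilt \cdot u}, \eqn{u = (r - r0)/w}, on
#'   the first heavy pair.
#' @param tether harmonic tether constant pinning each atom to its built
#'   geometry (0 disables).
#' @param temperature default sampling temperature (K).
#' @return a \code{toySpec} list.
#' @export
toySpec <- function(nHeavy = 2, hydrogens = 3, element = "C",
                    bondK = 300, bondR0 = 1.53, hBondK = 400,
                    hBondR0 = 1.09, angleK = 0, angleTheta0 = 1.9106,
                    ljEpsilon = 0, ljSigma = 3.4, ljMinSep = 3,
                    dwell = NULL, tether = 0, temperature = 300) {
  stopifnot(nHeavy >= 1, bondK > 0, hBondK > 0, ljSigma > 0)
  hydrogens <- rep_len(as.integer(hydrogens), nHeavy)
  if (any(hydrogens < 0) || any(hydrogens > 4))
    stop("unrealizable hydrogen pattern (0-4 hydrogens per site)")
  structure(list(nHeavy = as.integer(nHeavy), hydrogens = hydrogens,
                 element = element, bondK = bondK, bondR0 = bondR0,
                 hBondK = hBondK, hBondR0 = hBondR0, angleK = angleK,
                 angleTheta0 = angleTheta0, ljEpsilon = ljEpsilon,
                 ljSigma = ljSigma, ljMinSep = ljMinSep, dwell = dwell,
                 tether = tether, temperature = temperature),
            class = "toySpec")
}

# equilibrium heavy-heavy spacing: harmonic rest length, or the global
# minimum of the double-well bond
.heavySpacing <- function(spec) {
  if (is.null(spec$dwell)) return(spec$bondR0)
  dw <- spec$dwell
  opt <- stats::optimize(function(r) {
    u <- (r - dw$r0) / dw$w
    dw$h * (u^2 - 1)^2 + dw$tilt * u
  }, interval = c(dw$r0 - 2 * dw$w, dw$r0 + 2 * dw$w))
  opt$minimum
}

#' Build a toy molecule
#'
#' Constructs the topology and a near-minimum geometry for a
#' \code{\link{toySpec}}: heavy sites along the x axis at their equilibrium
#' spacing, hydrogens on tetrahedral-like unit directions at their bond
#' rest length. Construction is deterministic.
#'
#' @param spec a \code{\link{toySpec}}.
#' @return list with \code{topology} (a \linkS4class{Topology}) and
#'   \code{frame} (an \linkS4class{AllAtomFrame}).
#' @export
makeToyMolecule <- function(spec) {
  n <- spec$nHeavy
  sp <- .heavySpacing(spec)
  heavyPos <- cbind((seq_len(n) - 1) * sp, 0, 0)
  dirs <- rbind(c(-1, 1, 1), c(-1, -1, -1), c(-1, -1, 1), c(-1, 1, -1)) /
    sqrt(3)
  atoms <- data.frame(element = rep(spec$element, n), resid = seq_len(n),
                      resname = "TOY",
                      name = paste0(spec$element, seq_len(n)))
  xyz <- heavyPos
  bonds <- if (n > 1) cbind(seq_len(n - 1), 2:n) else NULL
  for (i in seq_len(n)) {
    k <- spec$hydrogens[i]
    if (k == 0) next
    d <- dirs[seq_len(k), , drop = FALSE]
    if (i == n && n > 1) d[, 1] <- -d[, 1] # point away from the chain
    if (i > 1 && i < n) d[, 1] <- 0
    d <- d / sqrt(rowSums(d^2))
    hIdx <- nrow(xyz) + seq_len(k)
    xyz <- rbind(xyz, heavyPos[rep(i, k), ] + spec$hBondR0 * d)
    atoms <- rbind(atoms, data.frame(element = rep("H", k), resid = i,
                                     resname = "TOY",
                                     name = paste0("H", i, seq_len(k))))
    bonds <- rbind(bonds, cbind(rep(i, k), hIdx))
  }
  list(topology = topology(atoms, bonds), frame = allAtomFrame(xyz))
}

#' Closed-form force field of a toy molecule
#'
#' Assembles the term tables of the analytic potential for a toy topology.
#'
#' @param spec a \code{\link{toySpec}}.
#' @param top the matching \linkS4class{Topology} (from
#'   \code{\link{makeToyMolecule}}).
#' @param referenceCoords geometry used for tether centers (defaults to
#'   the built geometry).
#' @return a \linkS4class{ToyForceField}.
#' @export
toyPotential <- function(spec, top = NULL, referenceCoords = NULL) {
  mol <- makeToyMolecule(spec)
  if (is.null(top)) top <- mol$topology
  if (is.null(referenceCoords)) referenceCoords <- coords(mol$frame)
  el <- top@atoms$element
  n <- spec$nHeavy
  bonds <- NULL; dwells <- NULL; angles <- NULL; lj <- NULL
  for (k in seq_len(nrow(top@bonds))) {
    i <- top@bonds[k, 1]; j <- top@bonds[k, 2]
    if (el[i] != "H" && el[j] != "H") {
      if (!is.null(spec$dwell) && i == 1 && j == 2)
        dwells <- rbind(dwells, c(1, 2, spec$dwell$h, spec$dwell$w,
                                  spec$dwell$r0, spec$dwell$tilt))
      else bonds <- rbind(bonds, c(i, j, spec$bondK, spec$bondR0))
    } else bonds <- rbind(bonds, c(i, j, spec$hBondK, spec$hBondR0))
  }
  if (spec$angleK > 0) { # H-X-H angles within each site
    for (i in seq_len(n)) {
      hs <- which(el == "H" & top@atoms$resid == i)
      if (length(hs) > 1) {
        prs <- utils::combn(hs, 2)
        angles <- rbind(angles, t(rbind(prs[1, ], i, prs[2, ],
                                        spec$angleK, spec$angleTheta0)))
      }
    }
  }
  if (spec$ljEpsilon > 0 && n > spec$ljMinSep) {
    for (i in seq_len(n - spec$ljMinSep))
      for (j in seq(i + spec$ljMinSep, n))
        lj <- rbind(lj, c(i, j, spec$ljEpsilon, spec$ljSigma))
  }
  tethers <- NULL; tcenters <- NULL
  if (spec$tether > 0) {
    tethers <- cbind(seq_along(el), spec$tether)
    tcenters <- referenceCoords
  }
  asMat <- function(x, k) if (is.null(x)) matrix(0, 0, k) else
    matrix(as.numeric(x), ncol = k)
  new("ToyForceField", terms = list(
    bonds = asMat(bonds, 4), dwells = asMat(dwells, 6),
    angles = asMat(angles, 5), lj = asMat(lj, 4),
    tethers = asMat(tethers, 2),
    tcenters = asMat(tcenters, 3)))
}

#' @describeIn potentialEnergy energy of a closed-form toy force field.
setMethod("potentialEnergy", c("ToyForceField", "matrix"),
  function(object, coords, ...) cpp_toy_energy(coords, object@terms))

#' @describeIn potentialEnergy energy of a toy force field for a frame.
setMethod("potentialEnergy", c("ToyForceField", "AllAtomFrame"),
  function(object, coords, ...)
    cpp_toy_energy(coords(coords), object@terms))

#' @describeIn potentialForces forces of a closed-form toy force field.
setMethod("potentialForces", c("ToyForceField", "matrix"),
  function(object, coords, ...) cpp_toy_forces(coords, object@terms))

#' @describeIn potentialForces forces of a toy force field for a frame.
setMethod("potentialForces", c("ToyForceField", "AllAtomFrame"),
  function(object, coords, ...)
    cpp_toy_forces(coords(coords), object@terms))

#' Analytic forces of a toy molecule
#'
#' Evaluates the closed-form force field at a conformation and returns the
#' frame with forces attached (double precision analytic gradients).
#'
#' @param top the toy \linkS4class{Topology}.
#' @param frame an \linkS4class{AllAtomFrame}.
#' @param spec the \code{\link{toySpec}}.
#' @return an \linkS4class{AllAtomFrame} with forces.
#' @export
toyForces <- function(top, frame, spec) {
  ff <- toyPotential(spec, top)
  allAtomFrame(coords(frame), potentialForces(ff, coords(frame)))
}

#' Atom masses of a toy topology
#'
#' @param top a \linkS4class{Topology}.
#' @return per-atom masses in a.m.u.
#' @export
atomMasses <- function(top) unname(.elementMasses[top@atoms$element])

#' Sample a coordinate--force dataset from a toy system
#'
#' Runs seeded Langevin dynamics of the closed-form all-atom potential and
#' records conformations every \code{sampleStride} steps after an
#' equilibration run, attaching the analytic forces (optionally corrupted
#' by Gaussian noise of known standard deviation for noise-floor studies).
#'
#' @param spec a \code{\link{toySpec}}.
#' @param nFrames number of frames to record.
#' @param temperature sampling temperature (K); defaults to the spec's.
#' @param seed RNG seed; the whole dataset is reproducible from
#'   (spec, seed).
#' @param dt all-atom timestep in fs (small enough for the stiff hydrogen
#'   bonds).
#' @param friction Langevin friction (1/ps).
#' @param equilSteps equilibration steps discarded before recording; a
#'   short run sets the \code{equilibrated} attribute to FALSE with a
#'   warning.
#' @param sampleStride steps between recorded frames.
#' @param noiseSigma standard deviation of optional i.i.d. Gaussian force
#'   noise (kcal/mol/A).
#' @return list with \code{topology}, \code{spec}, \code{coords} and
#'   \code{forces} (F x N x 3 arrays) and \code{temperature}; attribute
#'   \code{equilibrated}.
#' @export
sampleDataset <- function(spec, nFrames, temperature = spec$temperature,
                          seed = 1, dt = 0.5, friction = 10,
                          equilSteps = 4000, sampleStride = 10,
                          noiseSigma = 0) {
  stopifnot(nFrames >= 1)
  mol <- makeToyMolecule(spec)
  ff <- toyPotential(spec, mol$topology)
  masses <- atomMasses(mol$topology)
  st <- initState(coords(mol$frame), masses, temperature, seed = seed)
  eq <- runDynamics(st, ff, simConfig(timestep = dt, friction = friction,
                                      temperature = temperature,
                                      nSteps = equilSteps, seed = seed,
                                      outputStride = max(equilSteps, 1)))
  prod <- runDynamics(finalState(eq), ff,
                      simConfig(timestep = dt, friction = friction,
                                temperature = temperature,
                                nSteps = nFrames * sampleStride,
                                seed = seed + 1L,
                                outputStride = sampleStride))
  xyz <- coords(prod)[-1, , , drop = FALSE] # drop the initial frame
  N <- dim(xyz)[2]
  frc <- array(0, dim(xyz))
  for (f in seq_len(nFrames))
    frc[f, , ] <- cpp_toy_forces(xyz[f, , ], ff@terms)
  if (noiseSigma > 0)
    frc <- frc + withSeed(seed + 2L,
                          array(stats::rnorm(length(frc), 0, noiseSigma),
                                dim(frc)))
  equilibrated <- equilSteps * dt >= 1000 # >= 1 ps of equilibration
  if (!equilibrated)
    warning("short equilibration (", equilSteps * dt,
            " fs); dataset flagged as non-equilibrated")
  structure(list(topology = mol$topology, spec = spec, coords = xyz,
                 forces = frc, temperature = temperature),
            equilibrated = equilibrated)
}

#' Map a sampled toy dataset to a CG dataset
#'
#' Applies the noh map and basic force aggregation to every frame of a
#' \code{\link{sampleDataset}} result.
#'
#' @param sample result of \code{\link{sampleDataset}}.
#' @param table bead-type table (defaults to the canonical 12-class table;
#'   extended non-strictly for unusual toy compositions).
#' @return list with \code{dataset} (a \linkS4class{CGDataset}),
#'   \code{map} (the \linkS4class{CGMap}) and \code{nTypes}.
#' @export
mapSampleToCG <- function(sample, table = standardBeadTypeTable()) {
  map <- buildNohMap(sample$topology, table, strict = FALSE)
  agg <- aggregateForcesArray(sample$coords, sample$forces, map)
  nF <- dim(agg$coords)[1]
  frames <- lapply(seq_len(nF), function(f)
    cgFrame(agg$coords[f, , ], agg$beadTypes, agg$forces[f, , ]))
  list(dataset = cgDataset(frames, domain = "toy",
                           temperature = sample$temperature),
       map = map, nTypes = max(agg$beadTypes))
}

#' Analytic coarse-grained PMF of a two-site toy system
#'
#' For a two-heavy-site toy system whose hydrogens interact only within
#' their own bead, the bond-length potential of mean force is available in
#' closed form: the heavy-heavy pair potential plus, when
#' \code{jacobian = TRUE}, the radial entropy term \eqn{-2 k_B T \ln r}
#' that a bond-length histogram measures in three dimensions. The surface
#' is min-shifted to zero.
#'
#' @param spec a two-site \code{\link{toySpec}} (harmonic or double-well
#'   heavy bond).
#' @param grid reaction-coordinate grid (A); defaults to a window around
#'   the equilibrium spacing.
#' @param temperature temperature (K) for the Jacobian term.
#' @param jacobian include the \eqn{-2 k_B T \ln r} term.
#' @return an \linkS4class{AnalyticPMF}.
#' @export
analyticCgPmf <- function(spec, grid = NULL,
                          temperature = spec$temperature,
                          jacobian = TRUE) {
  if (spec$nHeavy != 2)
    stop("analytic PMF implemented for two-site systems only")
  pair <- .pairPotentialFunction(spec)
  if (is.null(grid)) {
    sp <- .heavySpacing(spec)
    w <- if (is.null(spec$dwell)) 4 * sqrt(.kB * temperature / spec$bondK)
         else 2.2 * spec$dwell$w
    grid <- seq(max(0.5, sp - w), sp + w, length.out = 201)
  }
  F_ <- pair(grid)
  if (jacobian) F_ <- F_ - 2 * .kB * temperature * log(grid)
  new("AnalyticPMF", grid = grid, energy = F_ - min(F_),
      description = if (is.null(spec$dwell)) "harmonic bond + Jacobian"
                    else "double-well bond + Jacobian")
}

.pairPotentialFunction <- function(spec) {
  if (is.null(spec$dwell)) {
    function(r) 0.5 * spec$bondK * (r - spec$bondR0)^2
  } else {
    dw <- spec$dwell
    function(r) {
      u <- (r - dw$r0) / dw$w
      dw$h * (u^2 - 1)^2 + dw$tilt * u
    }
  }
}

#' Basin free-energy difference of a double-well PMF
#'
#' Splits the reaction coordinate at the barrier top between the two wells
#' and computes the free-energy difference between the right and left
#' basins by numerical quadrature of the Boltzmann weight,
#' \eqn{\Delta F = -k_B T \ln (Z_{right} / Z_{left})}.
#'
#' @param spec a two-site double-well \code{\link{toySpec}}.
#' @param temperature temperature (K).
#' @return scalar free-energy difference in kcal/mol (positive when the
#'   right basin is less populated).
#' @export
basinDeltaF <- function(spec, temperature = spec$temperature) {
  if (is.null(spec$dwell)) stop("basinDeltaF needs a double-well spec")
  dw <- spec$dwell
  beta <- 1 / (.kB * temperature)
  pair <- .pairPotentialFunction(spec)
  dens <- function(r) exp(-beta * (pair(r) - 2 * .kB * temperature *
                                     log(r)))
  barrier <- stats::optimize(function(r) -pair(r),
                             interval = c(dw$r0 - dw$w * 0.95,
                                          dw$r0 + dw$w * 0.95))$minimum
  lo <- max(0.05, dw$r0 - 6 * dw$w); hi <- dw$r0 + 6 * dw$w
  zl <- stats::integrate(dens, lo, barrier, rel.tol = 1e-10)$value
  zr <- stats::integrate(dens, barrier, hi, rel.tol = 1e-10)$value
  -log(zr / zl) / beta
}

#' Two-site double-well dimer with a designed basin free-energy gap
#'
#' Builds the CG-solvable dimer benchmark: two heavy sites, each with
#' \code{hydrogens} stiffly bonded hydrogens, joined by a double-well bond
#' whose tilt is calibrated by quadrature so that the basin free-energy
#' difference of the exact PMF equals \code{deltaF} at the given
#' temperature.
#'
#' @param deltaF designed basin free-energy difference (kcal/mol).
#' @param h barrier height parameter (kcal/mol).
#' @param w well half-separation (A).
#' @param r0 barrier position (A).
#' @param hydrogens hydrogens per heavy site.
#' @param temperature reference temperature (K).
#' @return a calibrated \code{\link{toySpec}}.
#' @export
dimerSpec <- function(deltaF = 1, h = 2, w = 0.7, r0 = 4, hydrogens = 3,
                      temperature = 350) {
  mk <- function(tilt) toySpec(nHeavy = 2, hydrogens = hydrogens,
                               dwell = list(h = h, w = w, r0 = r0,
                                            tilt = tilt),
                               temperature = temperature)
  root <- stats::uniroot(function(t)
    basinDeltaF(mk(t), temperature) - deltaF,
    interval = c(-2, 2 * h + 2 * abs(deltaF) + 2), tol = 1e-12)
  mk(root$root)
}

#' Write an mdCATH-like fixture dataset
#'
#' Serializes per-domain groups (metadata attributes, bead types, one
#' coordinate/force array pair per temperature) into a single
#' self-describing fixture file in the layout read by
#' \code{\link{readFixtureDataset}} and \code{\link{domainSummary}}.
#'
#' @param domains named list of domain groups, each a list with
#'   \code{meta} (list: numResidues, numNohAtoms, helixFraction,
#'   sheetFraction), \code{types} (length-n integer) and
#'   \code{temperatures} (named list of lists with F x n x 3 \code{coords}
#'   and \code{forces}).
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeFixtureDataset <- function(domains, path) {
  saveRDS(list(format = "nohcg-fixture-1", domains = domains), path)
  invisible(path)
}

#' Generate a synthetic fixture domain group
#'
#' Builds one mdCATH-like domain group with controllable metadata and
#' seeded Gaussian coordinate/force arrays (statistical stand-ins, not
#' physical conformations).
#'
#' @param id domain id.
#' @param numResidues,numNohAtoms,helixFraction,sheetFraction metadata.
#' @param nFrames frames per temperature.
#' @param nBeads beads in the arrays (defaults to
#'   \code{min(numNohAtoms, 30)} to keep fixtures small).
#' @param temperatures numeric temperatures (K).
#' @param seed RNG seed.
#' @return a domain group list for \code{\link{writeFixtureDataset}}.
#' @export
makeFixtureDomain <- function(id, numResidues, numNohAtoms,
                              helixFraction, sheetFraction, nFrames = 5,
                              nBeads = min(numNohAtoms, 30),
                              temperatures = c(320, 348, 379, 413, 450),
                              seed = 1) {
  withSeed(seed, {
    temps <- lapply(temperatures, function(t)
      list(coords = array(stats::rnorm(nFrames * nBeads * 3, sd = 5),
                          c(nFrames, nBeads, 3)),
           forces = array(stats::rnorm(nFrames * nBeads * 3, sd = 10),
                          c(nFrames, nBeads, 3))))
    names(temps) <- as.character(temperatures)
    list(meta = list(numResidues = numResidues,
                     numNohAtoms = numNohAtoms,
                     helixFraction = helixFraction,
                     sheetFraction = sheetFraction),
         types = sample.int(12, nBeads, replace = TRUE),
         temperatures = temps)
  })
}
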