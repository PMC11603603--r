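#' End-to-end dimer benchmark: map, train, simulate, compare to the
#' analytic PMF
#'
#' Runs the package's flagship consistency check on the CG-solvable toy
#' dimer: (1) sample all-atom coordinate--force data from the closed-form
#' force field, pooling several sampling temperatures for coverage (the
#' labels are exact analytic forces, so pooling only broadens the sampled
#' configurations); (2) apply the noh map with basic force aggregation;
#' (3) train the radial-basis pair potential by variational force
#' matching; (4) run a long Langevin simulation of the two-bead system
#' under the trained potential with the aggregated bead masses; and (5)
#' compare the simulated bond-length free energy with the analytic PMF
#' (pair potential plus radial Jacobian) over the populated bins.
#'
#' @param seed master RNG seed.
#' @param nFrames total training frames (split over the sampling
#'   temperatures).
#' @param samplingTemperatures all-atom sampling temperatures (K).
#' @param temperature CG simulation temperature (K); also the reference
#'   temperature of the designed basin free-energy gap.
#' @param deltaF designed basin free-energy difference (kcal/mol).
#' @param epochs conjugate-gradient training epochs.
#' @param nSteps CG simulation steps.
#' @param timestep CG timestep (fs).
#' @param friction CG friction (1/ps).
#' @param outputStride CG frames saved every this many steps.
#' @param minCount bins with fewer simulation frames are treated as
#'   unpopulated.
#' @param nBins histogram bins over the analytically relevant range.
#' @return list with \code{maxError} (max abs PMF deviation, kcal/mol,
#'   over populated bins), \code{pmf} (data.frame: r, analytic,
#'   simulated, count), \code{fit} (training result),
#'   \code{trainLoss}, \code{spec}, \code{map}.
#' @export
runDimerBenchmark <- function(seed = 1, nFrames = 50000,
                              samplingTemperatures = c(320, 348, 379,
                                                       413, 450),
                              temperature = 300, deltaF = 1,
                              epochs = 300,
                              nSteps = 1e6, timestep = 4, friction = 1,
                              outputStride = 10, minCount = 50,
                              nBins = 45) {
  spec <- dimerSpec(deltaF = deltaF, temperature = temperature)
  perT <- ceiling(nFrames / length(samplingTemperatures))
  samples <- lapply(seq_along(samplingTemperatures), function(i)
    sampleDataset(spec, perT, temperature = samplingTemperatures[i],
                  seed = seed + 137L * i))
  cgParts <- lapply(samples, mapSampleToCG)
  map <- cgParts[[1]]$map
  dataset <- cgDataset(
    unlist(lapply(cgParts, function(p) p$dataset@frames),
           recursive = FALSE),
    domain = "dimer",
    temperature = rep(samplingTemperatures,
                      vapply(cgParts, function(p) nFrames(p$dataset), 0)))
  split <- strideAndSplit(dataset, stride = 1,
                          fractions = c(0.9, 0.05, 0.05), seed = seed)
  pot <- radialPairPotential(nTypes = max(beadTypes(map)), cutoff = 10,
                             rmin = 2.2, rmax = 6.8, nBasis = 16)
  fit <- trainPotential(pot, split$train, split$val, epochs = epochs)
  # CG simulation of the dimer under the trained potential
  start <- split$train@frames[[1]]
  st <- initState(start, beadMasses(map), temperature, seed = seed + 7L)
  traj <- runDynamics(st, fit$model,
                      simConfig(timestep = timestep, friction = friction,
                                temperature = temperature,
                                nSteps = nSteps, seed = seed + 11L,
                                outputStride = outputStride))
  xyz <- coords(traj)
  drop <- floor(dim(xyz)[1] * 0.10) # discard initial frames
  xyz <- xyz[(drop + 1):dim(xyz)[1], , , drop = FALSE]
  rSim <- sqrt((xyz[, 1, 1] - xyz[, 2, 1])^2 +
               (xyz[, 1, 2] - xyz[, 2, 2])^2 +
               (xyz[, 1, 3] - xyz[, 2, 3])^2)
  # histogram over the analytically relevant window (analytic F <= 4.5)
  pmfFull <- analyticCgPmf(spec, temperature = temperature)
  keep <- pmfFull@energy <= 4.5
  edges <- seq(min(pmfFull@grid[keep]), max(pmfFull@grid[keep]),
               length.out = nBins + 1)
  mids <- 0.5 * (edges[-1] + edges[-length(edges)])
  idx <- findInterval(rSim, edges, rightmost.closed = TRUE)
  counts <- tabulate(idx[idx >= 1 & idx <= nBins], nBins)
  kT <- .kB * temperature
  fSim <- -kT * log(counts / sum(counts))
  pair <- .pairPotentialFunction(spec)
  fAna <- pair(mids) - 2 * kT * log(mids)
  pop <- counts >= minCount
  fSim <- fSim - min(fSim[pop])
  fAna <- fAna - min(fAna[pop])
  maxError <- max(abs(fSim[pop] - fAna[pop]))
  list(maxError = maxError,
       pmf = data.frame(r = mids, analytic = fAna, simulated = fSim,
                        count = counts, populated = pop),
       fit = fit,
       trainLoss = utils::tail(fit$history$train, 1),
       nTrainFrames = nFrames(split$train),
       spec = spec, map = map, traj = traj)
}
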