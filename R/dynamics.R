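#' Simulation configuration
#'
#' Settings of the Langevin engine. Units follow the package convention:
#' timestep in fs, friction in 1/ps, temperature in K.
#'
#' @param timestep integration timestep in fs (default 4).
#' @param friction Langevin friction coefficient in 1/ps (default 1);
#'   0 gives microcanonical velocity-Verlet dynamics.
#' @param temperature thermostat temperature in K (default 350).
#' @param nSteps number of integration steps.
#' @param seed RNG seed for the thermostat noise.
#' @param outputStride save a frame every this many steps.
#' @param saveVelocities keep velocities in the trajectory.
#' @return a named list of settings.
#' @export
simConfig <- function(timestep = 4, friction = 1, temperature = 350,
                      nSteps = 1000, seed = 1, outputStride = 1,
                      saveVelocities = FALSE) {
  stopifnot(timestep > 0, friction >= 0, nSteps >= 0, outputStride >= 1)
  list(timestep = timestep, friction = friction,
       temperature = temperature, nSteps = as.integer(nSteps),
       seed = as.integer(seed), outputStride = as.integer(outputStride),
       saveVelocities = isTRUE(saveVelocities))
}

#' Initialize a simulation state
#'
#' Draws initial velocities from the Maxwell--Boltzmann distribution at the
#' requested temperature with the per-bead masses (zero velocities at
#' T = 0). Reproducible from \code{seed}.
#'
#' @param frame a \linkS4class{CGFrame} (or n x 3 coordinate matrix).
#' @param masses per-bead masses in a.m.u., or a \linkS4class{CGMap} whose
#'   aggregated bead masses are used.
#' @param temperature temperature in K.
#' @param seed RNG seed.
#' @param beadTypes optional integer types (taken from \code{frame} when it
#'   is a CGFrame).
#' @return a \linkS4class{SimState}.
#' @export
initState <- function(frame, masses, temperature, seed = 1,
                      beadTypes = NULL) {
  x <- if (is(frame, "CGFrame")) coords(frame) else as.matrix(frame)
  if (is(frame, "CGFrame") && is.null(beadTypes))
    beadTypes <- beadTypes(frame)
  if (is(masses, "CGMap")) masses <- beadMasses(masses)
  n <- nrow(x)
  if (length(masses) != n) stop("one mass per bead required")
  if (temperature < 0) stop("temperature must be >= 0")
  v <- if (temperature == 0) matrix(0, n, 3) else
    withSeed(seed, matrix(stats::rnorm(3 * n), n, 3) *
               sqrt(.kB * temperature * .accFactor / masses))
  if (is.null(beadTypes)) beadTypes <- rep(1L, n)
  new("SimState", coords = x, velocities = v, masses = as.numeric(masses),
      beadTypes = as.integer(beadTypes), step = 0L)
}

.ffArgs <- function(object, state) {
  if (is(object, "RadialPairPotential"))
    list(kind = "rbf", types = .checkTypes(object, state@beadTypes),
         nTypes = object@nTypes, coef = object@coef,
         centers = object@centers, width = object@width,
         cutoff = object@cutoff)
  else if (is(object, "ToyForceField"))
    list(kind = "toy", terms = object@terms)
  else stop("unsupported potential class: ", class(object))
}

#' One BAOAB Langevin step
#'
#' Advances the state by a single step of the BAOAB splitting of Langevin
#' dynamics. With zero friction and zero temperature the update reduces to
#' velocity Verlet. Thermostat noise is drawn from R's RNG, so steps are
#' reproducible under \code{set.seed} and match \code{\link{runDynamics}}
#' draw for draw.
#'
#' @param state a \linkS4class{SimState}.
#' @param object the potential.
#' @param config a \code{\link{simConfig}} list.
#' @return the updated \linkS4class{SimState}.
#' @export
langevinStep <- function(state, object, config) {
  dt <- config$timestep
  gamma <- config$friction / 1000 # 1/ps -> 1/fs
  n <- nrow(state@coords)
  x <- state@coords; v <- state@velocities
  invm <- .accFactor / state@masses
  F_ <- potentialForces(object, x, types = state@beadTypes)
  if (!all(is.finite(F_))) stop("non-finite force at step ", state@step)
  v <- v + 0.5 * dt * F_ * invm
  x <- x + 0.5 * dt * v
  c1 <- exp(-gamma * dt)
  c2 <- sqrt(1 - c1^2)
  sig <- sqrt(.kB * config$temperature * .accFactor / state@masses)
  v <- c1 * v + c2 * sig * matrix(stats::rnorm(3 * n), n, 3)
  x <- x + 0.5 * dt * v
  F_ <- potentialForces(object, x, types = state@beadTypes)
  if (!all(is.finite(F_))) stop("non-finite force at step ", state@step)
  v <- v + 0.5 * dt * F_ * invm
  initState2 <- state
  initState2@coords <- x; initState2@velocities <- v
  initState2@step <- state@step + 1L
  initState2
}

#' Run Langevin dynamics
#'
#' Propagates the state for \code{config$nSteps} BAOAB steps under the
#' given potential, saving a frame (and its potential energy) every
#' \code{config$outputStride} steps, the initial frame included. The run
#' is deterministic given \code{config$seed}; the returned trajectory
#' carries the final state so runs can be restarted.
#'
#' @inheritParams langevinStep
#' @return a \linkS4class{Trajectory}.
#' @export
runDynamics <- function(state, object, config) {
  ff <- .ffArgs(object, state)
  res <- withSeed(config$seed, {
    if (ff$kind == "rbf")
      cpp_run_rbf(state@coords, state@velocities, state@masses,
                  config$timestep, config$friction / 1000,
                  config$temperature, config$nSteps, config$outputStride,
                  config$saveVelocities, ff$types, ff$nTypes, ff$coef,
                  ff$centers, ff$width, ff$cutoff)
    else
      cpp_run_toy(state@coords, state@velocities, state@masses,
                  config$timestep, config$friction / 1000,
                  config$temperature, config$nSteps, config$outputStride,
                  config$saveVelocities, ff$terms)
  })
  nSaved <- dim(res$coords)[1]
  finalState <- state
  finalState@coords <- res$finalCoords
  finalState@velocities <- res$finalVelocities
  finalState@step <- state@step + config$nSteps
  new("Trajectory", coords = res$coords,
      velocities = if (config$saveVelocities) res$velocities else NULL,
      energies = res$energies,
      times = (seq_len(nSaved) - 1) * config$outputStride *
        config$timestep,
      config = c(config, list(finalState = finalState,
                              beadTypes = state@beadTypes,
                              masses = state@masses)))
}

#' Final state of a trajectory
#'
#' @param traj a \linkS4class{Trajectory}.
#' @return the \linkS4class{SimState} at the last integration step, usable
#'   to restart \code{\link{runDynamics}}.
#' @export
finalState <- function(traj) traj@config$finalState

#' Write / read a trajectory
#'
#' Self-describing single-file serialization of a trajectory (coordinates,
#' optional velocities, per-frame potential energies, configuration
#' attributes). Lossless round trip.
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param path file path.
#' @export
writeTrajectory <- function(traj, path) {
  saveRDS(list(format = "nohcg-traj-1", coords = traj@coords,
               velocities = traj@velocities, energies = traj@energies,
               times = traj@times, config = traj@config), path)
  invisible(path)
}

#' @rdname writeTrajectory
#' @export
readTrajectory <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "nohcg-traj-1"))
    stop("not a trajectory file: missing or wrong 'format' marker")
  new("Trajectory", coords = obj$coords, velocities = obj$velocities,
      energies = obj$energies, times = obj$times, config = obj$config)
}

#' Kinetic temperature of a state or velocity set
#'
#' @param state a \linkS4class{SimState}.
#' @return instantaneous kinetic temperature in K.
#' @export
kineticTemperature <- function(state) {
  ke <- 0.5 * sum(state@masses * rowSums(state@velocities^2)) /
    .accFactor # -> kcal/mol
  2 * ke / (3 * nrow(state@coords) * .kB)
}
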