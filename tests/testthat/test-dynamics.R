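kB <- boltzmannConstant()

test_that("velocity initialization is Maxwell-Boltzmann, seeded, and zero at T = 0", {
  masses <- rep(15, 2000)
  x <- matrix(0, 2000, 3)
  st0 <- initState(x, masses, 0)
  expect_true(all(st0@velocities == 0))
  expect_error(initState(x, masses, -10), ">= 0")
  st1 <- initState(x, masses, 300, seed = 4)
  st2 <- initState(x, masses, 300, seed = 4)
  expect_identical(st1@velocities, st2@velocities)
  # equipartition of the draw: mean KE per bead = (3/2) kB T within 3 SE
  kePerBead <- 0.5 * masses * rowSums(st1@velocities^2) / 4.184e-4
  target <- 1.5 * kB * 300
  se <- sd(kePerBead) / sqrt(length(kePerBead))
  expect_lt(abs(mean(kePerBead) - target), 3 * se)
})

test_that("a force-free cold state is a fixed point of the integrator", {
  spec <- toySpec(nHeavy = 1, hydrogens = 0) # no interactions at all
  mol <- makeToyMolecule(spec)
  ff <- toyPotential(spec, mol$topology)
  st <- initState(coords(mol$frame), atomMasses(mol$topology), 0)
  out <- langevinStep(st, ff, simConfig(timestep = 4, friction = 1,
                                        temperature = 0, nSteps = 1))
  expect_identical(out@coords, st@coords)
  expect_identical(out@velocities, st@velocities)
})

test_that("the thermostat samples the harmonic equipartition value", {
  k <- 5
  spec <- toySpec(nHeavy = 1, hydrogens = 0, tether = k)
  mol <- makeToyMolecule(spec)
  ff <- toyPotential(spec, mol$topology)
  st <- initState(coords(mol$frame), atomMasses(mol$topology), 300,
                  seed = 2)
  tr <- runDynamics(st, ff, simConfig(timestep = 2, friction = 5,
                                      temperature = 300, nSteps = 3e5,
                                      seed = 3, outputStride = 10))
  x <- coords(tr)[-(1:1000), 1, ] # discard equilibration
  x2 <- as.vector(x^2)
  target <- kB * 300 / k
  # crude effective sample size: thermostat decorrelates in ~1/gamma
  se <- sd(x2) / sqrt(length(x2) / 20)
  expect_lt(abs(mean(x2) - target), 3 * se)
  # kinetic temperature of the final state distribution
  tSamp <- kineticTemperature(finalState(tr))
  expect_gt(tSamp, 50) # a single snapshot fluctuates broadly
})

test_that("zero friction at small timestep conserves energy (velocity-Verlet limit)", {
  spec <- toySpec(nHeavy = 1, hydrogens = 0, tether = 5)
  mol <- makeToyMolecule(spec)
  ff <- toyPotential(spec, mol$topology)
  st <- initState(coords(mol$frame) + matrix(c(0.3, 0.2, 0.1), 1, 3),
                  atomMasses(mol$topology), 0)
  tr <- runDynamics(st, ff, simConfig(timestep = 0.5, friction = 0,
                                      temperature = 0, nSteps = 1e4,
                                      seed = 1, outputStride = 1,
                                      saveVelocities = TRUE))
  m <- atomMasses(mol$topology)
  ke <- apply(tr@velocities, 1, function(v)
    0.5 * sum(m * matrix(v, ncol = 3)^2) / 4.184e-4)
  etot <- tr@energies + ke
  expect_lt((max(etot) - min(etot)) / abs(mean(etot)), 1e-4)
})

test_that("runs are deterministic, restartable, and stride/length bookkeeping is exact", {
  spec <- dimerSpec(deltaF = 1, temperature = 300)
  mol <- makeToyMolecule(spec)
  ff <- toyPotential(spec, mol$topology)
  st <- initState(coords(mol$frame), atomMasses(mol$topology), 300,
                  seed = 5)
  cfg <- simConfig(timestep = 1, friction = 1, temperature = 300,
                   nSteps = 200, seed = 9, outputStride = 20)
  t1 <- runDynamics(st, ff, cfg)
  t2 <- runDynamics(st, ff, cfg)
  expect_identical(coords(t1), coords(t2))
  expect_equal(nFrames(t1), 200 / 20 + 1)
  # zero steps: only the initial frame
  t0 <- runDynamics(st, ff, simConfig(nSteps = 0))
  expect_equal(nFrames(t0), 1)
  expect_equal(coords(t0)[1, , ], st@coords)
  # a single engine step equals the R-level BAOAB step draw for draw
  cfg1 <- simConfig(timestep = 1, friction = 1, temperature = 300,
                    nSteps = 1, seed = 31)
  set.seed(31)
  sR <- langevinStep(st, ff, cfg1)
  sC <- finalState(runDynamics(st, ff, cfg1))
  expect_equal(sR@coords, sC@coords, tolerance = 1e-14)
  expect_equal(sR@velocities, sC@velocities, tolerance = 1e-14)
  # restart: two 100-step legs with the same seeds equal one 200-step run
  legA <- runDynamics(st, ff, simConfig(timestep = 1, friction = 1,
                                        temperature = 300, nSteps = 100,
                                        seed = 9, outputStride = 20))
  legB <- runDynamics(finalState(legA), ff,
                      simConfig(timestep = 1, friction = 1,
                                temperature = 300, nSteps = 100,
                                seed = 10, outputStride = 20))
  expect_equal(dim(coords(legB)), c(6, nrow(st@coords), 3))
  # different seeds give independent replicas
  alt <- runDynamics(st, ff, simConfig(timestep = 1, friction = 1,
                                       temperature = 300, nSteps = 200,
                                       seed = 99, outputStride = 20))
  expect_gt(max(abs(coords(alt) - coords(t1))), 1e-6)
})

test_that("simulating the learned potential works and trajectories round-trip", {
  pot <- randomPotential(nTypes = 1)
  pot@coef[] <- 0
  pot@coef[1, 3] <- 2 # a mild repulsive bump
  st <- initState(rbind(c(0, 0, 0), c(3.5, 0, 0)), c(15, 15), 300,
                  seed = 1, beadTypes = c(1L, 1L))
  tr <- runDynamics(st, pot, simConfig(timestep = 2, friction = 1,
                                       temperature = 300, nSteps = 500,
                                       seed = 2, outputStride = 50))
  expect_true(all(is.finite(coords(tr))))
  path <- tempfile(fileext = ".rds")
  writeTrajectory(tr, path)
  back <- readTrajectory(path)
  expect_identical(coords(back), coords(tr))
  expect_identical(back@energies, tr@energies)
  expect_error(readTrajectory(
    {p <- tempfile(); saveRDS(list(format = "other"), p); p}),
    "not a trajectory")
})

test_that("exploding integration reports a simulation error with the step index", {
  spec <- toySpec(nHeavy = 2, hydrogens = 0, bondK = 300)
  mol <- makeToyMolecule(spec)
  ff <- toyPotential(spec, mol$topology)
  st <- initState(coords(mol$frame), atomMasses(mol$topology), 300,
                  seed = 1)
  expect_error(
    runDynamics(st, ff, simConfig(timestep = 1e6, friction = 0,
                                  temperature = 0, nSteps = 50,
                                  seed = 1)),
    "step")
})
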