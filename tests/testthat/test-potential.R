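test_that("energy is invariant under rigid motions and bead reindexing", {
  set.seed(11)
  pot <- randomPotential()
  for (rep in 1:10) {
    fr <- randomCGFrame(6)
    e0 <- potentialEnergy(pot, fr)
    R <- testRotation()
    t_ <- rnorm(3, sd = 5)
    xR <- sweep(coords(fr) %*% t(R), 2, -t_)
    expect_equal(potentialEnergy(pot, xR, types = beadTypes(fr)), e0,
                 tolerance = 1e-10)
    # shuffled bead order with consistently permuted types
    p <- sample(nBeads(fr))
    expect_equal(potentialEnergy(pot, coords(fr)[p, ],
                                 types = beadTypes(fr)[p]), e0,
                 tolerance = 1e-12)
  }
})

test_that("energy matches an independent pure-R evaluation", {
  set.seed(12)
  pot <- randomPotential(nTypes = 3)
  for (rep in 1:5) {
    fr <- randomCGFrame(5, nTypes = 3)
    expect_equal(potentialEnergy(pot, fr),
                 referenceEnergy(pot, coords(fr), beadTypes(fr)),
                 tolerance = 1e-12)
  }
})

test_that("beads beyond the receptive field do not interact", {
  pot <- randomPotential(cutoff = 6)
  x <- rbind(c(0, 0, 0), c(10, 0, 0)) # farther apart than the cutoff
  expect_equal(potentialEnergy(pot, x, types = c(1L, 2L)), 0)
  expect_true(all(potentialForces(pot, x, types = c(1L, 2L)) == 0))
})

test_that("forces are the exact negative gradient and transform equivariantly", {
  set.seed(13)
  pot <- randomPotential()
  fr <- randomCGFrame(5)
  x <- coords(fr); types <- beadTypes(fr)
  F_ <- potentialForces(pot, x, types = types)
  # central finite differences, step 1e-4 A
  h <- 1e-4
  for (i in 1:5) for (d in 1:3) {
    xp <- x; xp[i, d] <- xp[i, d] + h
    xm <- x; xm[i, d] <- xm[i, d] - h
    fd <- -(potentialEnergy(pot, xp, types = types) -
            potentialEnergy(pot, xm, types = types)) / (2 * h)
    expect_lt(abs(fd - F_[i, d]), 1e-3)
  }
  # translation invariance, rotation equivariance, zero total force
  expect_equal(potentialForces(pot, sweep(x, 2, -c(3, 1, -2)),
                               types = types), F_, tolerance = 1e-10)
  R <- testRotation()
  expect_equal(potentialForces(pot, x %*% t(R), types = types),
               F_ %*% t(R), tolerance = 1e-9)
  expect_equal(colSums(F_), c(0, 0, 0), tolerance = 1e-12)
})

test_that("unknown bead types are a typing error", {
  pot <- randomPotential(nTypes = 2)
  x <- matrix(rnorm(6), 2, 3)
  expect_error(potentialEnergy(pot, x, types = c(1L, 5L)),
               "unknown bead type")
  expect_error(potentialForces(pot, x, types = c(0L, 1L)),
               "unknown bead type")
})

test_that("force-matching loss follows the per-component normalization", {
  # exact match
  f <- matrix(rnorm(9), 3, 3)
  expect_equal(forceMatchingLoss(f, f), 0)
  # single bead, residual (3,0,0): 9 / 3 components
  expect_equal(forceMatchingLoss(matrix(c(3, 0, 0), 1, 3),
                                 matrix(0, 1, 3)), 3)
  # random batch vs naive double loop
  set.seed(14)
  K <- 4
  pred <- lapply(c(2, 3, 5, 1), function(n) matrix(rnorm(3 * n), n, 3))
  lab <- lapply(pred, function(p) p + matrix(rnorm(length(p)), nrow(p), 3))
  naive <- 0
  for (k in 1:K) {
    s <- 0
    for (i in seq_len(nrow(pred[[k]]))) for (d in 1:3)
      s <- s + (pred[[k]][i, d] - lab[[k]][i, d])^2
    naive <- naive + s / (3 * nrow(pred[[k]]))
  }
  naive <- naive / K
  expect_equal(forceMatchingLoss(pred, lab), naive, tolerance = 1e-12)
  # invariant to conformation order
  p <- sample(K)
  expect_equal(forceMatchingLoss(pred[p], lab[p]),
               forceMatchingLoss(pred, lab))
  # errors
  expect_error(forceMatchingLoss(list(), list()), "empty batch")
  expect_error(forceMatchingLoss(pred[1:2], lab[1]), "differ in length")
})

test_that("training recovers the generating coefficients of a linear-basis potential", {
  set.seed(15)
  truth <- randomPotential(nTypes = 1, nBasis = 6, cutoff = 8)
  frames <- lapply(1:300, function(i) {
    fr <- randomCGFrame(4, nTypes = 1, box = 6)
    cgFrame(coords(fr), beadTypes(fr),
            potentialForces(truth, coords(fr), types = beadTypes(fr)))
  })
  ds <- cgDataset(frames)
  fit <- trainPotential(radialPairPotential(1, cutoff = 8, rmin = 1.5,
                                            rmax = 7, nBasis = 6),
                        ds, epochs = 300)
  # independent closed-form least squares: design built by a pure-R loop
  X <- NULL; y <- NULL
  for (fr in frames[1:150]) {
    x <- coords(fr); n <- nrow(x)
    D <- matrix(0, 3 * n, 6)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      dx <- x[i, ] - x[j, ]
      r <- sqrt(sum(dx^2))
      if (r >= truth@cutoff) next
      g <- exp(-(r - truth@centers)^2 / (2 * truth@width^2))
      fc <- 0.5 * (1 + cos(pi * r / truth@cutoff))
      dphi <- g * (-(r - truth@centers) / truth@width^2) * fc +
        g * (-0.5 * pi / truth@cutoff * sin(pi * r / truth@cutoff))
      for (d in 1:3) {
        D[(d - 1) * n + i, ] <- D[(d - 1) * n + i, ] - dphi * dx[d] / r
        D[(d - 1) * n + j, ] <- D[(d - 1) * n + j, ] + dphi * dx[d] / r
      }
    }
    X <- rbind(X, D)
    y <- c(y, as.vector(forces(fr)))
  }
  s <- svd(X)
  thetaLS <- s$v %*% ((crossprod(s$u, y)) / s$d)
  thetaHat <- as.vector(fit$model@coef)
  expect_lt(sqrt(sum((thetaHat - thetaLS)^2) / sum(thetaLS^2)), 0.01)
  # and the least-squares solution is the generator itself (clean labels)
  expect_lt(sqrt(sum((thetaLS - as.vector(truth@coef))^2) /
                   sum(truth@coef^2)), 0.01)
})

test_that("all-zero labels drive the trained model to the zero-force predictor", {
  set.seed(16)
  frames <- lapply(1:50, function(i) {
    fr <- randomCGFrame(3, nTypes = 1, box = 5)
    cgFrame(coords(fr), beadTypes(fr), matrix(0, 3, 3))
  })
  ds <- cgDataset(frames)
  start <- randomPotential(nTypes = 1, nBasis = 5)
  fit <- trainPotential(start, ds, val = ds, epochs = 100)
  expect_lt(tail(fit$history$val, 1), 1e-8)
  expect_gt(fit$history$val[1], tail(fit$history$val, 1))
  # no hidden prior terms: the trained-to-zero model predicts zero force
  fr <- randomCGFrame(4, nTypes = 1, box = 5)
  expect_lt(max(abs(potentialForces(fit$model, coords(fr),
                                    types = beadTypes(fr)))), 1e-4)
})

test_that("training on a noisy dimer dataset reaches the injected noise floor", {
  sigma <- 0.5
  spec <- dimerSpec(deltaF = 1, temperature = 300)
  s <- sampleDataset(spec, 2000, temperature = 400, seed = 21,
                     noiseSigma = sigma)
  cg <- mapSampleToCG(s)
  pot <- radialPairPotential(max(beadTypes(cg$map)), cutoff = 10,
                             rmin = 2.2, rmax = 6.8, nBasis = 16)
  fit <- trainPotential(pot, cg$dataset, epochs = 200)
  # the model cannot fit i.i.d. atomic noise; aggregation over the 4
  # atoms of each CH3 bead sets the loss floor at 4 sigma^2
  floorVar <- 4 * sigma^2
  finalLoss <- tail(fit$history$train, 1)
  expect_lt(finalLoss, floorVar * 1.1)
  expect_gt(finalLoss, floorVar * 0.8)
  # force RMSE against the *clean* labels is below the noise floor
  clean <- mapSampleToCG(sampleDataset(spec, 2000, temperature = 400,
                                       seed = 21))
  pred <- lapply(clean$dataset@frames, function(fr)
    potentialForces(fit$model, fr))
  lab <- lapply(clean$dataset@frames, forces)
  expect_lt(sqrt(forceMatchingLoss(pred, lab)), sqrt(floorVar))
})

test_that("force evaluation reports overall and per-type MAE", {
  set.seed(17)
  pot <- randomPotential(nTypes = 2)
  frames <- lapply(1:10, function(i) {
    fr <- randomCGFrame(5, nTypes = 2)
    cgFrame(coords(fr), beadTypes(fr),
            potentialForces(pot, coords(fr), types = beadTypes(fr)))
  })
  ds <- cgDataset(frames)
  ev <- evaluateForces(pot, ds)
  expect_equal(ev$mae, 0)
  # constant offset (1,1,1) on all predictions shifts the MAE to 1
  shifted <- cgDataset(lapply(frames, function(fr)
    cgFrame(coords(fr), beadTypes(fr), forces(fr) + 1)))
  ev1 <- evaluateForces(pot, shifted)
  expect_equal(ev1$mae, 1, tolerance = 1e-12)
  expect_equal(ev1$byType$mae, c(1, 1), tolerance = 1e-12)
  # per-type grouping matches a manual split
  noisy <- cgDataset(lapply(frames, function(fr)
    cgFrame(coords(fr), beadTypes(fr),
            forces(fr) + matrix(rnorm(15), 5, 3))))
  ev2 <- evaluateForces(pot, noisy)
  allT <- unlist(lapply(noisy@frames, beadTypes))
  allE <- abs(do.call(rbind, lapply(seq_along(frames), function(k)
    potentialForces(pot, noisy@frames[[k]]) -
      forces(noisy@frames[[k]]))))
  for (t in 1:2)
    expect_equal(ev2$byType$mae[ev2$byType$type == t],
                 mean(allE[allT == t, ]))
  expect_error(evaluateForces(pot, cgDataset(list())), "empty")
})
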