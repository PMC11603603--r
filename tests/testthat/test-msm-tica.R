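test_that("C-alpha distance features have the right combinatorics and invariances", {
  set.seed(21)
  x <- array(rnorm(10 * 4 * 3, sd = 3), c(10, 4, 3))
  f <- featurizeCaDistances(x, select = 1:3)
  expect_equal(ncol(f), 3) # 3 choose 2
  # manual distances on the first frame
  d12 <- sqrt(sum((x[1, 1, ] - x[1, 2, ])^2))
  d13 <- sqrt(sum((x[1, 1, ] - x[1, 3, ])^2))
  d23 <- sqrt(sum((x[1, 2, ] - x[1, 3, ])^2))
  expect_equal(f[1, ], c(d12, d13, d23))
  # rigid motion per frame leaves features unchanged
  R <- testRotation()
  xr <- x
  for (t in 1:10) xr[t, , ] <- sweep(x[t, , ] %*% t(R), 2, -c(4, 1, 2))
  expect_equal(featurizeCaDistances(xr, select = 1:3), f,
               tolerance = 1e-10)
  # CA selection from a topology
  top <- buildPeptideTopology("AG")
  xa <- array(rnorm(10 * nAtoms(top) * 3), c(10, nAtoms(top), 3))
  expect_equal(ncol(featurizeCaDistances(xa, topology = top)), 1)
  expect_error(featurizeCaDistances(x, select = 1), "at least 2")
})

test_that("TICA reproduces a dense generalized eigensolver and the degenerate limit", {
  set.seed(22)
  # trajectories that are constant in time: lagged covariance equals the
  # instantaneous one, so every eigenvalue is 1
  const <- lapply(1:300, function(i) {
    v <- rnorm(3)
    rbind(v, v)
  })
  m0 <- ticaFit(const, lag = 1)
  expect_equal(m0@eigenvalues, rep(1, 3), tolerance = 1e-8)
  # random data: our whitened symmetric solve vs solve(C0, Ctau)
  X <- matrix(rnorm(2000 * 4), 2000, 4) %*% matrix(rnorm(16), 4, 4)
  m <- ticaFit(X, lag = 3)
  oracle <- sort(Re(eigen(solve(m@c0, m@ctau))$values),
                 decreasing = TRUE)
  expect_equal(m@eigenvalues, oracle, tolerance = 1e-8)
  # eigenvalues are sorted descending and generalized-orthonormal
  expect_true(all(diff(m@eigenvalues) <= 1e-12))
  G <- t(m@vectors) %*% m@c0 %*% m@vectors
  expect_equal(G, diag(4), tolerance = 1e-8)
})

test_that("TICA identifies the slow direction of an OU mixture", {
  set.seed(23)
  n <- 30000
  ou <- function(n, tau) {
    a <- exp(-1 / tau); s <- sqrt(1 - a^2)
    x <- numeric(n)
    for (t in 2:n) x[t] <- a * x[t - 1] + s * rnorm(1)
    x
  }
  slow <- ou(n, 100); fast <- ou(n, 2)
  A <- matrix(c(1, 0.5, 0.3, 1), 2, 2)
  X <- cbind(slow, fast) %*% t(A)
  m <- ticaFit(X, lag = 10)
  proj <- ticaTransform(m, X, 1)
  expect_gt(abs(cor(proj[, 1], slow)), 0.99)
  expect_gt(m@eigenvalues[1], m@eigenvalues[2] + 0.5)
})

test_that("CG projection reuses the all-atom basis without refitting", {
  set.seed(24)
  X <- matrix(rnorm(500 * 3), 500, 3)
  m <- ticaFit(X, lag = 2)
  # projecting the training features equals the transform
  expect_equal(projectCG(m, X, 2), ticaTransform(m, X, 2))
  # features at the mean project to the origin
  expect_equal(as.vector(projectCG(m, matrix(m@mean, 1), 3)),
               rep(0, 3), tolerance = 1e-12)
  # a shifted copy moves linearly along the projection vectors
  delta <- c(1, -2, 0.5)
  shift <- projectCG(m, sweep(X, 2, -delta), 2) - projectCG(m, X, 2)
  expected <- rep(1, 500) %o% as.vector(delta %*% m@vectors[, 1:2])
  expect_equal(shift, expected, tolerance = 1e-10)
  expect_error(projectCG(m, X[, 1:2]), "dimension mismatch")
})

test_that("K-means microstates are seeded, deterministic and separate blobs", {
  set.seed(25)
  blobs <- rbind(matrix(rnorm(400, 0, 0.3), 200, 2),
                 matrix(rnorm(400, 5, 0.3), 200, 2))
  cl <- clusterMicrostates(blobs, 2, seed = 7)
  expect_equal(length(unique(cl$labels[1:200])), 1)
  expect_equal(length(unique(cl$labels[201:400])), 1)
  expect_false(cl$labels[1] == cl$labels[400])
  cl2 <- clusterMicrostates(blobs, 2, seed = 7)
  expect_identical(cl$labels, cl2$labels)
  expect_true(is.finite(cl$inertia))
  one <- clusterMicrostates(blobs, 1)
  expect_true(all(one$labels == 1L))
  expect_error(clusterMicrostates(blobs, 0), "positive")
  expect_error(clusterMicrostates(blobs, 500), "exceeds")
})

test_that("MSM estimation recovers an analytic telegraph process", {
  set.seed(26)
  n <- 200000; p12 <- 0.05; p21 <- 0.02
  s <- integer(n); s[1] <- 1L
  r <- runif(n)
  for (t in 2:n)
    s[t] <- if (s[t - 1] == 1L) (if (r[t] < p12) 2L else 1L)
            else (if (r[t] < p21) 1L else 2L)
  msm <- estimateMSM(s, lag = 1, discardFraction = 0.10)
  # rows sum to one exactly
  expect_lt(max(abs(rowSums(msm@transition) - 1)), 1e-12)
  # transition probabilities within 3 standard errors of the truth
  n1 <- sum(s == 1)
  se12 <- sqrt(p12 * (1 - p12) / n1)
  se21 <- sqrt(p21 * (1 - p21) / (n - n1))
  expect_lt(abs(msm@transition[1, 2] - p12), 3 * se12)
  expect_lt(abs(msm@transition[2, 1] - p21), 3 * se21)
  # stationary distribution and detailed balance
  expect_equal(msm@stationary,
               c(p21, p12) / (p12 + p21), tolerance = 0.02)
  flux <- msm@stationary * msm@transition
  expect_lt(max(abs(flux - t(flux))), 1e-12)
  expect_equal(as.vector(msm@stationary %*% msm@transition),
               msm@stationary, tolerance = 1e-10)
})

test_that("MSM edge cases: constant trajectory, discard fraction, connectivity", {
  msm1 <- estimateMSM(rep(1L, 100), lag = 1)
  expect_equal(msm1@transition, matrix(1, 1, 1))
  # a state confined to the discarded initial 10% disappears
  lab <- c(rep(3L, 10), rep(1:2, 45))
  msm2 <- suppressMessages(estimateMSM(lab, lag = 1,
                                       discardFraction = 0.10))
  expect_false(3L %in% msm2@states)
  # disconnected halves: the larger component is kept and reported
  lab3 <- list(rep(1:2, 30), rep(3L, 100))
  expect_message(estimateMSM(lab3, lag = 1, discardFraction = 0),
                 "largest connected")
})

test_that("free-energy surfaces are weight-scale invariant with an exact zero minimum", {
  set.seed(27)
  P <- matrix(rnorm(1e6), ncol = 2) # standard 2-D Gaussian
  fes <- freeEnergySurface(P, grid = 80, temperature = 300)
  expect_equal(dim(fes@energy), c(80, 80))
  expect_equal(min(fes@energy, na.rm = TRUE), 0)
  # doubling the weights changes nothing
  fes2 <- freeEnergySurface(P, weights = rep(2, nrow(P)), grid = 80)
  expect_equal(fes2@energy, fes@energy)
  # the populated surface is quadratic: R^2 > 0.95 on the 80 x 80 grid
  xc <- 0.5 * (fes@xEdges[-1] + fes@xEdges[-81])
  yc <- 0.5 * (fes@yEdges[-1] + fes@yEdges[-81])
  g <- expand.grid(x = xc, y = yc)
  z <- as.vector(fes@energy)
  # populated bins: at least 10 samples (recounted independently)
  ix <- findInterval(P[, 1], fes@xEdges, rightmost.closed = TRUE)
  iy <- findInterval(P[, 2], fes@yEdges, rightmost.closed = TRUE)
  counts <- as.vector(table(factor(ix, 1:80), factor(iy, 1:80)))
  ok <- !is.na(z) & counts >= 10
  fit <- lm(z[ok] ~ I(g$x[ok]^2) + I(g$y[ok]^2) + g$x[ok] + g$y[ok])
  expect_gt(summary(fit)$r.squared, 0.95)
  # single point: its bin is 0, everything else empty
  one <- freeEnergySurface(matrix(c(0.5, 0.5), 1), grid = 4,
                           edges = list(x = 0:4 / 4, y = 0:4 / 4))
  expect_equal(sum(!is.na(one@energy)), 1)
  expect_equal(one@energy[3, 3], 0)
  expect_error(freeEnergySurface(P[0, , drop = FALSE]), "no projections")
  expect_error(freeEnergySurface(P[1:5, ], weights = rep(0, 5)),
               "all weights are zero")
})

test_that("frame weights redistribute the stationary distribution over frames", {
  set.seed(28)
  lab <- sample(1:3, 300, replace = TRUE)
  msm <- estimateMSM(lab, lag = 1, discardFraction = 0)
  w <- frameWeights(msm, lab)
  expect_equal(sum(w), 1)
  for (s in seq_along(msm@states))
    expect_equal(sum(w[lab == msm@states[s]]), msm@stationary[s],
                 tolerance = 1e-12)
})

test_that("macrostate statistics locate the native state via Kabsch RMSD", {
  set.seed(29)
  ref <- matrix(rnorm(12, sd = 2), 4, 3)
  other <- ref + matrix(rnorm(12, sd = 1.5), 4, 3)
  R <- testRotation(); if (det(R) < 0) R[, 1] <- -R[, 1]
  frames <- array(0, c(60, 4, 3))
  lab <- integer(60)
  for (t in 1:60) {
    base <- if (t %% 2 == 0) ref else other
    lab[t] <- if (t %% 2 == 0) 1L else 2L
    frames[t, , ] <- sweep(base %*% t(R), 2, -c(1, 2, 3))
  }
  msm <- estimateMSM(lab, lag = 1, discardFraction = 0)
  msm <- assignMacrostates(msm, 2, seed = 1)
  out <- macrostateStats(msm, frames, lab, ref)
  # frames equal to the reference (up to a rigid motion) have RMSD 0
  expect_lt(min(out$rmsd), 1e-8)
  expect_equal(out$rmsd[2], 0, tolerance = 1e-8)
  # the native macrostate is the one holding the reference conformation
  nativeMicro <- 1L
  expect_equal(out$native,
               msm@macrostates[match(nativeMicro, msm@states)])
  expect_equal(sum(out$table$probability), 1, tolerance = 1e-10)
  # independent oracles: bio3d superposition (reports 3 decimals) and a
  # direct numerical minimization over proper rotations
  oracle <- bio3d::rmsd(as.vector(t(ref)), as.vector(t(other)),
                        fit = TRUE)
  expect_equal(round(out$rmsd[1], 3), oracle)
  a <- sweep(ref, 2, colMeans(ref))
  b <- sweep(other, 2, colMeans(other))
  eulerRMSD <- function(p) {
    cx <- cos(p[1]); sx <- sin(p[1]); cy <- cos(p[2]); sy <- sin(p[2])
    cz <- cos(p[3]); sz <- sin(p[3])
    R <- matrix(c(cy * cz, cy * sz, -sy,
                  sx * sy * cz - cx * sz, sx * sy * sz + cx * cz, sx * cy,
                  cx * sy * cz + sx * sz, cx * sy * sz - sx * cz, cx * cy),
                3, 3, byrow = TRUE)
    sqrt(mean(rowSums((a - b %*% R)^2)))
  }
  numOracle <- min(vapply(1:10, function(i)
    optim(runif(3, -pi, pi), eulerRMSD, method = "Nelder-Mead",
          control = list(maxit = 2000, reltol = 1e-14))$value, 0))
  expect_equal(out$rmsd[1], numOracle, tolerance = 1e-6)
  # residue-range selection restricts the comparison set
  sel <- macrostateStats(msm, frames, lab, ref, select = 1:3)
  expect_lt(min(sel$rmsd), 1e-8)
  expect_error(macrostateStats(msm, frames, lab, ref[1:3, ]),
               "differ")
})
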