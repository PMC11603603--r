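# Shared test helpers: small topologies and independent oracles.

# topology of a single heavy atom with k bonded hydrogens
oneBead <- function(element = "C", k = 3) {
  atoms <- data.frame(element = c(element, rep("H", k)))
  bonds <- if (k > 0) cbind(1L, 1L + seq_len(k)) else
    matrix(integer(), 0, 2)
  topology(atoms, bonds)
}

# random O(3) matrix (Haar via QR), possibly a reflection
testRotation <- function() {
  q <- qr(matrix(rnorm(9), 3, 3))
  qr.Q(q) %*% diag(sign(diag(qr.R(q))))
}

# independent brute-force aggregation: loop over beads and their hydrogens
bruteAggregate <- function(f, map) {
  hv <- heavyIndices(map)
  out <- matrix(0, length(hv), 3)
  for (i in seq_along(hv)) {
    out[i, ] <- f[hv[i], ]
    for (h in hydrogenSets(map)[[i]])
      out[i, ] <- out[i, ] + f[h, ]
  }
  out
}

# random CG frame with given bead count/types spread over a box
randomCGFrame <- function(n, nTypes = 2, box = 8, withForces = FALSE) {
  cgFrame(matrix(runif(3 * n, 0, box), n, 3),
          sample.int(nTypes, n, replace = TRUE),
          if (withForces) matrix(rnorm(3 * n), n, 3) else NULL)
}

# random radial-basis potential with non-trivial coefficients
randomPotential <- function(nTypes = 2, nBasis = 6, cutoff = 8) {
  pot <- radialPairPotential(nTypes, cutoff = cutoff, rmin = 1.5,
                             rmax = cutoff - 1, nBasis = nBasis)
  pot@coef <- matrix(rnorm(length(pot@coef), sd = 0.3),
                     nrow(pot@coef), ncol(pot@coef))
  pot
}

# independent radial-basis evaluation (pure R, mirrors the documented form)
referenceEnergy <- function(pot, x, types) {
  U <- 0
  n <- nrow(x)
  P <- pot@nTypes
  pIdx <- function(a, b) {
    if (a > b) { t <- a; a <- b; b <- t }
    (a - 1) * P - (a - 1) * (a - 2) / 2 + (b - a) + 1
  }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    r <- sqrt(sum((x[i, ] - x[j, ])^2))
    if (r >= pot@cutoff) next
    phi <- exp(-(r - pot@centers)^2 / (2 * pot@width^2)) *
      0.5 * (1 + cos(pi * r / pot@cutoff))
    U <- U + sum(pot@coef[pIdx(types[i], types[j]), ] * phi)
  }
  U
}

# fixture domains: metadata chosen so exactly trainPass survive the
# training filters
fixtureDomainSet <- function() {
  list(
    d1 = makeFixtureDomain("d1", 120, 900, 0.4, 0.2, nFrames = 4,
                           temperatures = c(320, 450), seed = 11),
    d2 = makeFixtureDomain("d2", 150, 1000, 0.25, 0.25, nFrames = 4,
                           temperatures = c(320, 450), seed = 12),
    d3 = makeFixtureDomain("d3", 200, 1500, 0.9, 0.05, nFrames = 4,
                           temperatures = c(320, 450), seed = 13),
    d4 = makeFixtureDomain("d4", 100, 800, 0.1, 0.1, nFrames = 4,
                           temperatures = c(320, 450), seed = 14),
    d5 = makeFixtureDomain("d5", 151, 950, 0.6, 0.1, nFrames = 4,
                           temperatures = c(320, 450), seed = 15))
}
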