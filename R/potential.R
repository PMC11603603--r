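#' Construct an invariant radial-basis pair potential
#'
#' The energy is a sum over bead pairs within the receptive field
#' (\code{cutoff}) of Gaussian radial basis functions of the pair distance,
#' smoothly switched off at the cutoff by a cosine envelope, with one
#' coefficient vector per unordered pair of bead types:
#' \deqn{U(R, z) = \sum_{i<j, r_{ij} < r_c} \sum_m \theta_{p(z_i, z_j), m}
#'   \, e^{-(r_{ij}-\mu_m)^2 / 2w^2} \, \tfrac12 (1 + \cos(\pi r_{ij}/r_c)).}
#' Forces are the exact analytic negative gradient. Because the energy
#' depends on coordinates only through interbead distances it is invariant
#' under rotations, reflections and translations, and beads farther apart
#' than the cutoff do not interact.
#'
#' @param nTypes number of bead types.
#' @param cutoff receptive field in Angstrom (default 10).
#' @param rmin center of the innermost basis function (Angstrom).
#' @param rmax center of the outermost basis function (defaults to the
#'   cutoff; placing it at the edge of the sampled distance range avoids
#'   dead basis functions).
#' @param nBasis number of radial basis functions.
#' @param width Gaussian width; defaults to the center spacing.
#' @param coef optional coefficient matrix (pair types x basis); defaults
#'   to zeros.
#' @return a \linkS4class{RadialPairPotential}.
#' @export
radialPairPotential <- function(nTypes, cutoff = 10, rmin = 1,
                                rmax = cutoff, nBasis = 16, width = NULL,
                                coef = NULL) {
  nTypes <- as.integer(nTypes)
  centers <- seq(rmin, rmax, length.out = nBasis)
  if (is.null(width)) width <- centers[2] - centers[1]
  P <- nTypes * (nTypes + 1L) / 2L
  if (is.null(coef)) coef <- matrix(0, P, nBasis)
  new("RadialPairPotential", nTypes = nTypes, centers = centers,
      width = width, cutoff = cutoff, coef = coef)
}

.checkTypes <- function(object, types) {
  if (any(types < 1L | types > object@nTypes))
    stop("unknown bead type(s): ",
         paste(unique(types[types < 1L | types > object@nTypes]),
               collapse = ", "))
  as.integer(types)
}

#' @describeIn potentialEnergy energy of a radial-basis pair potential for
#'   an n x 3 coordinate matrix; \code{types} gives per-bead types.
#' @param types integer bead types (matrix-coordinate methods).
setMethod("potentialEnergy", c("RadialPairPotential", "matrix"),
  function(object, coords, types, ...) {
    types <- .checkTypes(object, types)
    cpp_rbf_energy(coords, types, object@nTypes, object@coef,
                   object@centers, object@width, object@cutoff)
  })

#' @describeIn potentialEnergy energy of a CG frame.
setMethod("potentialEnergy", c("RadialPairPotential", "CGFrame"),
  function(object, coords, ...)
    potentialEnergy(object, coords(coords), beadTypes(coords)))

#' @describeIn potentialForces forces of a radial-basis pair potential.
#' @param types integer bead types (matrix-coordinate methods).
setMethod("potentialForces", c("RadialPairPotential", "matrix"),
  function(object, coords, types, ...) {
    types <- .checkTypes(object, types)
    cpp_rbf_forces(coords, types, object@nTypes, object@coef,
                   object@centers, object@width, object@cutoff)
  })

#' @describeIn potentialForces forces for a CG frame.
setMethod("potentialForces", c("RadialPairPotential", "CGFrame"),
  function(object, coords, ...)
    potentialForces(object, coords(coords), beadTypes(coords)))

#' Force design matrix of the linear potential
#'
#' For the radial-basis pair potential the predicted force vector is linear
#' in the coefficients: \code{vec(F) = D \%*\% vec(coef)} with the
#' column-major flattenings of the n x 3 force matrix and of the
#' coefficient matrix. Exposed for closed-form fits and diagnostics.
#'
#' @param object a \linkS4class{RadialPairPotential}.
#' @param coords n x 3 coordinates.
#' @param types integer bead types.
#' @return a (3 n) x (nPairTypes * nBasis) matrix.
#' @export
forceDesignMatrix <- function(object, coords, types) {
  types <- .checkTypes(object, types)
  P <- object@nTypes * (object@nTypes + 1L) / 2L
  cpp_rbf_design(coords, types, object@nTypes, P, object@centers,
                 object@width, object@cutoff)
}

#' Force-matching loss
#'
#' The variational force-matching objective: the mean over the K
#' conformations of a batch of the squared force deviation, normalized per
#' bead and per Cartesian component,
#' \deqn{L = \frac{1}{K} \sum_{k=1}^{K} \frac{1}{3 N_k}
#'   \sum_{i=1}^{N_k} \lVert F^{pred}_{k,i} - F^{lab}_{k,i} \rVert^2,}
#' in units of (kcal/mol/A)^2. Mean over components (the 1/3) keeps the
#' loss scale independent of dimensionality; the alternative per-bead
#' normalization differs only by a constant factor 3.
#'
#' @param predicted,labeled lists of n_k x 3 force matrices (a single
#'   matrix is treated as a one-conformation batch).
#' @return scalar loss.
#' @export
forceMatchingLoss <- function(predicted, labeled) {
  if (is.matrix(predicted)) predicted <- list(predicted)
  if (is.matrix(labeled)) labeled <- list(labeled)
  K <- length(predicted)
  if (K == 0) stop("empty batch")
  if (length(labeled) != K)
    stop("predicted and labeled batches differ in length")
  tot <- 0
  for (k in seq_len(K)) {
    if (!identical(dim(predicted[[k]]), dim(labeled[[k]])))
      stop("shape mismatch in conformation ", k)
    d <- predicted[[k]] - labeled[[k]]
    tot <- tot + sum(d * d) / (3 * nrow(d))
  }
  tot / K
}

# Sufficient statistics of the quadratic force-matching objective over a
# dataset: loss(theta) = theta' A theta - 2 b' theta + c.
.lossStats <- function(object, dataset) {
  K <- nFrames(dataset)
  if (K == 0) stop("empty dataset")
  p <- length(object@coef)
  A <- matrix(0, p, p); b <- numeric(p); cc <- 0
  for (k in seq_len(K)) {
    fr <- dataset@frames[[k]]
    if (is.null(fr@forces)) stop("frame ", k, " has no force labels")
    D <- forceDesignMatrix(object, coords(fr), beadTypes(fr))
    y <- as.vector(fr@forces)
    w <- 1 / (3 * nBeads(fr) * K)
    A <- A + w * crossprod(D)
    b <- b + w * crossprod(D, y)[, 1]
    cc <- cc + w * sum(y * y)
  }
  list(A = A, b = b, c = cc)
}

#' Train a potential by variational force matching
#'
#' Minimizes the force-matching loss over the training set iteratively.
#' For the linear radial-basis potential the loss is an exact quadratic in
#' the coefficients, so its value and full-batch gradient are computed
#' from sufficient statistics accumulated in one pass over the data; each
#' epoch is one optimizer update. Two optimizers are provided:
#' \describe{
#'   \item{\code{cg}}{conjugate gradient on the quadratic objective
#'     (default). From a zero start it converges to the minimum-norm
#'     least-squares solution even when parts of the basis see no data.}
#'   \item{\code{adam}}{full-batch Adam with learning rate \code{lr};
#'     robust but slow on ill-conditioned bases.}
#' }
#' The coefficients with the best validation loss are retained. Training
#' is deterministic: both optimizers use the exact full-batch gradient and
#' draw no randomness.
#'
#' @param object a \linkS4class{RadialPairPotential} (its coefficients are
#'   the starting point).
#' @param train,val \linkS4class{CGDataset}s with force labels; \code{val}
#'   may be NULL, in which case the training loss selects the checkpoint.
#' @param epochs number of optimizer updates.
#' @param method \code{"cg"} or \code{"adam"}.
#' @param lr learning rate (Adam only).
#' @param beta1,beta2,epsilon Adam moment parameters.
#' @return list with \code{model} (the trained potential), \code{history}
#'   (data.frame of per-epoch train/validation losses) and
#'   \code{bestEpoch}.
#' @export
trainPotential <- function(object, train, val = NULL, epochs = 500,
                           method = c("cg", "adam"), lr = 0.05,
                           beta1 = 0.9, beta2 = 0.999, epsilon = 1e-8) {
  method <- match.arg(method)
  st <- .lossStats(object, train)
  sv <- if (is.null(val)) NULL else .lossStats(object, val)
  theta <- as.vector(object@coef)
  lossOf <- function(s, th) drop(th %*% s$A %*% th - 2 * sum(s$b * th) +
                                   s$c)
  hist <- data.frame(epoch = seq_len(epochs), train = NA_real_,
                     val = NA_real_)
  best <- list(loss = Inf, theta = theta, epoch = 0L)
  if (method == "adam") m <- v <- numeric(length(theta))
  else { # conjugate gradient state: residual of A theta = b
    r <- st$b - (st$A %*% theta)[, 1]
    p <- r
    rs <- sum(r * r)
  }
  for (e in seq_len(epochs)) {
    if (method == "adam") {
      g <- 2 * (st$A %*% theta - st$b)[, 1]
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g * g
      mh <- m / (1 - beta1^e); vh <- v / (1 - beta2^e)
      theta <- theta - lr * mh / (sqrt(vh) + epsilon)
    } else if (rs > 0) {
      Ap <- (st$A %*% p)[, 1]
      pAp <- sum(p * Ap)
      if (pAp > 0) {
        alpha <- rs / pAp
        theta <- theta + alpha * p
        r <- r - alpha * Ap
        rsNew <- sum(r * r)
        p <- r + (rsNew / rs) * p
        rs <- rsNew
      } else rs <- 0
    }
    trLoss <- lossOf(st, theta)
    if (!is.finite(trLoss)) stop("training diverged at epoch ", e)
    hist$train[e] <- trLoss
    sel <- trLoss
    if (!is.null(sv)) {
      hist$val[e] <- lossOf(sv, theta)
      sel <- hist$val[e]
    }
    if (sel < best$loss) best <- list(loss = sel, theta = theta, epoch = e)
  }
  object@coef <- matrix(best$theta, nrow(object@coef), ncol(object@coef))
  list(model = object, history = hist, bestEpoch = best$epoch)
}

#' Evaluate force errors of a potential on a dataset
#'
#' Mean absolute error of the predicted forces, assessed per Cartesian
#' component over all beads and frames, plus the same MAE grouped by bead
#' type.
#'
#' @param object a potential with a \code{\link{potentialForces}} method.
#' @param dataset a \linkS4class{CGDataset} with force labels.
#' @return list with \code{mae} (overall, kcal/mol/A) and \code{byType}
#'   (data.frame with columns \code{type}, \code{mae}, \code{n}).
#' @export
evaluateForces <- function(object, dataset) {
  K <- nFrames(dataset)
  if (K == 0) stop("empty dataset")
  absErr <- list(); typeOf <- list()
  for (k in seq_len(K)) {
    fr <- dataset@frames[[k]]
    if (is.null(fr@forces)) stop("frame ", k, " has no force labels")
    e <- abs(potentialForces(object, fr) - fr@forces)
    absErr[[k]] <- e
    typeOf[[k]] <- beadTypes(fr)
  }
  allErr <- do.call(rbind, absErr)
  types <- unlist(typeOf)
  byType <- do.call(rbind, lapply(sort(unique(types)), function(t) {
    sel <- types == t
    data.frame(type = t, mae = mean(allErr[sel, , drop = FALSE]),
               n = sum(sel))
  }))
  list(mae = mean(allErr), byType = byType)
}
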