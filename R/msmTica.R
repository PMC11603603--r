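#' Pairwise C-alpha distance features
#'
#' Featurizes a trajectory by all unique pairwise distances between
#' C-alpha (or otherwise selected) beads, one column per unordered pair in
#' i < j lexicographic order. The features are invariant under rigid
#' motions of each frame.
#'
#' @param x an F x n x 3 coordinate array, an n x 3 matrix (one frame), or
#'   a \linkS4class{Trajectory}.
#' @param select indices of the atoms/beads to use; alternatively supply
#'   \code{topology} and atoms named \code{CA} are selected.
#' @param topology optional \linkS4class{Topology} used to locate CA
#'   atoms.
#' @return F x (m choose 2) feature matrix.
#' @export
featurizeCaDistances <- function(x, select = NULL, topology = NULL) {
  if (is(x, "Trajectory")) x <- coords(x)
  if (is.matrix(x)) x <- array(x, c(1, dim(x)))
  if (is.null(select)) {
    if (is.null(topology))
      select <- seq_len(dim(x)[2])
    else select <- which(topology@atoms$name == "CA" &
                           topology@atoms$element != "H")
  }
  m <- length(select)
  if (m < 2) stop("at least 2 C-alpha sites are required")
  prs <- utils::combn(m, 2)
  out <- matrix(0, dim(x)[1], ncol(prs))
  for (p in seq_len(ncol(prs))) {
    i <- select[prs[1, p]]; j <- select[prs[2, p]]
    out[, p] <- sqrt((x[, i, 1] - x[, j, 1])^2 +
                     (x[, i, 2] - x[, j, 2])^2 +
                     (x[, i, 3] - x[, j, 3])^2)
  }
  out
}

.asTrajList <- function(features) {
  if (is.list(features)) features else list(features)
}

#' Fit time-lagged independent component analysis
#'
#' Estimates the symmetrized instantaneous and time-lagged covariance
#' matrices of the features at lag \code{lag} and solves the generalized
#' eigenproblem \eqn{C_\tau w = \lambda C_0 w}. Symmetrized estimation
#' keeps the eigenvalues real and at most 1; components are ordered by
#' decreasing eigenvalue (slowest first).
#'
#' A near-singular instantaneous covariance is regularized by adding a
#' small multiple of the identity (reported via a message) unless
#' \code{strict = TRUE}, in which case it is an error.
#'
#' @param features F x d feature matrix, or a list of such matrices (one
#'   per trajectory).
#' @param lag lag time in frames (>= 1).
#' @param epsilon relative regularization strength.
#' @param strict error instead of regularizing a singular covariance.
#' @return a \linkS4class{TICAModel}.
#' @export
ticaFit <- function(features, lag, epsilon = 1e-10, strict = FALSE) {
  stopifnot(lag >= 1)
  trajs <- .asTrajList(features)
  d <- ncol(trajs[[1]])
  s1 <- numeric(d); n <- 0
  for (X in trajs) {
    if (nrow(X) <= lag) next
    t0 <- seq_len(nrow(X) - lag)
    s1 <- s1 + colSums(X[t0, , drop = FALSE]) +
      colSums(X[t0 + lag, , drop = FALSE])
    n <- n + length(t0)
  }
  if (n == 0) stop("no frame pairs at this lag")
  mu <- s1 / (2 * n)
  C0 <- matrix(0, d, d); Ct <- matrix(0, d, d)
  for (X in trajs) {
    if (nrow(X) <= lag) next
    t0 <- seq_len(nrow(X) - lag)
    A <- sweep(X[t0, , drop = FALSE], 2, mu)
    B <- sweep(X[t0 + lag, , drop = FALSE], 2, mu)
    C0 <- C0 + crossprod(A) + crossprod(B)
    Ct <- Ct + crossprod(A, B) + crossprod(B, A)
  }
  C0 <- C0 / (2 * n); Ct <- Ct / (2 * n)
  e0 <- eigen(C0, symmetric = TRUE)
  tol <- max(e0$values) * 1e-12
  if (any(e0$values < tol)) {
    if (strict) stop("singular instantaneous covariance")
    message("regularizing singular covariance (epsilon = ", epsilon, ")")
    e0$values <- e0$values + epsilon * max(e0$values)
  }
  L <- e0$vectors %*% diag(1 / sqrt(e0$values), d)
  M <- crossprod(L, Ct %*% L)
  em <- eigen((M + t(M)) / 2, symmetric = TRUE)
  ord <- order(em$values, decreasing = TRUE)
  new("TICAModel", mean = mu, c0 = C0, ctau = Ct,
      eigenvalues = em$values[ord],
      vectors = L %*% em$vectors[, ord, drop = FALSE],
      lag = as.integer(lag))
}

#' Project features with a fitted TICA model
#'
#' @param model a \linkS4class{TICAModel}.
#' @param features F x d feature matrix in the model's feature space.
#' @param nComponents number of leading components to return.
#' @return F x nComponents projection matrix.
#' @export
ticaTransform <- function(model, features, nComponents = 2) {
  if (ncol(features) != length(model@mean))
    stop("feature dimension mismatch: model has ", length(model@mean),
         ", input has ", ncol(features))
  sweep(features, 2, model@mean) %*%
    model@vectors[, seq_len(nComponents), drop = FALSE]
}

#' Project coarse-grained features with all-atom TICA covariances
#'
#' Applies the feature means and projection vectors fitted on all-atom
#' data to CG features in the same feature space (pairwise C-alpha
#' distances) without refitting, so CG and all-atom trajectories share one
#' reduced space.
#'
#' @inheritParams ticaTransform
#' @param cgFeatures CG feature matrix.
#' @return projection matrix.
#' @export
projectCG <- function(model, cgFeatures, nComponents = 3)
  ticaTransform(model, cgFeatures, nComponents)

# k-means++ seeding
.kmeansppCenters <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(0, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1), ]
  d2 <- rowSums(sweep(x, 2, centers[1, ])^2)
  for (j in seq_len(k - 1) + 1) {
    p <- d2 / sum(d2)
    centers[j, ] <- x[sample.int(n, 1, prob = p), ]
    d2 <- pmin(d2, rowSums(sweep(x, 2, centers[j, ])^2))
  }
  centers
}

#' Discretize projections into microstates by K-means
#'
#' Seeded, deterministic K-means with k-means++ initialization.
#'
#' @param projections F x m projection matrix.
#' @param k number of microstates (1 <= k <= F).
#' @param seed RNG seed.
#' @return list with integer \code{labels} (1..k), \code{inertia} (total
#'   within-cluster sum of squares) and \code{centers}.
#' @export
clusterMicrostates <- function(projections, k, seed = 1) {
  projections <- as.matrix(projections)
  if (k <= 0) stop("k must be positive")
  if (k > nrow(projections)) stop("k exceeds the number of frames")
  uniq <- unique(projections)
  if (nrow(uniq) <= k) { # degenerate: every distinct point is a center
    lab <- match(apply(projections, 1, paste, collapse = "\r"),
                 apply(uniq, 1, paste, collapse = "\r"))
    return(list(labels = as.integer(lab), inertia = 0, centers = uniq))
  }
  withSeed(seed, {
    init <- .kmeansppCenters(projections, k)
    km <- suppressWarnings(
      stats::kmeans(projections, centers = init, iter.max = 100))
    list(labels = as.integer(km$cluster), inertia = km$tot.withinss,
         centers = km$centers)
  })
}

# largest connected component of the symmetrized count graph
.largestConnected <- function(C) {
  n <- nrow(C)
  adj <- (C + t(C)) > 0
  comp <- integer(n); cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  sizes <- tabulate(comp)
  which(comp == which.max(sizes))
}

#' Estimate a Markov state model
#'
#' Discards the leading \code{discardFraction} of each trajectory (to
#' remove starting-structure bias), counts sliding-window transitions at
#' the lag, restricts to the largest connected state set, and estimates a
#' reversible transition matrix by iterative maximum likelihood on the
#' count matrix (the stationary distribution is then available in closed
#' form and satisfies detailed balance). With \code{reversible = FALSE}
#' the row-normalized count matrix is used and the stationary distribution
#' is taken from the leading left eigenvector.
#'
#' @param labels integer microstate labels, or a list of label vectors
#'   (one per trajectory).
#' @param lag lag time in frames (>= 1).
#' @param discardFraction fraction of initial frames dropped per
#'   trajectory (e.g. 0.10; use 0.05 for long-trajectory systems).
#' @param reversible use the reversible maximum-likelihood estimator.
#' @param maxIter,tol iteration controls for the reversible estimator.
#' @return an \linkS4class{MSMResult}.
#' @export
estimateMSM <- function(labels, lag, discardFraction = 0.10,
                        reversible = TRUE, maxIter = 10000, tol = 1e-12) {
  stopifnot(lag >= 1, discardFraction >= 0, discardFraction < 1)
  trajs <- .asTrajList(labels)
  nStates <- max(unlist(trajs))
  C <- matrix(0, nStates, nStates)
  for (l in trajs) {
    drop <- floor(length(l) * discardFraction)
    l <- l[(drop + 1):length(l)]
    if (length(l) <= lag) next
    t0 <- seq_len(length(l) - lag)
    for (k in t0) C[l[k], l[k + lag]] <- C[l[k], l[k + lag]] + 1
  }
  active <- .largestConnected(C)
  visited <- which(rowSums(C) + colSums(C) > 0)
  active <- intersect(active, visited)
  if (length(active) < nStates)
    message("restricting to largest connected set: ", length(active),
            " of ", nStates, " states")
  C <- C[active, active, drop = FALSE]
  if (reversible) {
    Cs <- C + t(C)
    x <- Cs / sum(Cs)
    ci <- rowSums(C)
    for (it in seq_len(maxIter)) {
      xi <- rowSums(x)
      xNew <- Cs / (outer(ci / xi, ci / xi, "+"))
      xNew[Cs == 0] <- 0
      xNew <- xNew / sum(xNew)
      delta <- max(abs(xNew - x))
      x <- xNew
      if (delta < tol) break
    }
    pi_ <- rowSums(x)
    T_ <- x / pi_
  } else {
    T_ <- C / rowSums(C)
    ev <- eigen(t(T_))
    k <- which.max(Re(ev$values))
    pi_ <- Re(ev$vectors[, k]); pi_ <- pi_ / sum(pi_)
  }
  new("MSMResult", transition = T_, lag = as.integer(lag),
      stationary = as.numeric(pi_), states = as.integer(active),
      counts = C, macrostates = integer())
}

#' Lump microstates into macrostates
#'
#' Spectral lumping: K-means (k-means++ seeded) on the leading right
#' eigenvectors of the transition matrix assigns each microstate of the
#' active set to one of \code{nMacro} metastable macrostates.
#'
#' @param msm an \linkS4class{MSMResult}.
#' @param nMacro number of macrostates.
#' @param seed RNG seed.
#' @return the \linkS4class{MSMResult} with its \code{macrostates} slot
#'   filled (one assignment per active microstate).
#' @export
assignMacrostates <- function(msm, nMacro, seed = 1) {
  ev <- eigen(msm@transition)
  ord <- order(Re(ev$values), decreasing = TRUE)
  V <- Re(ev$vectors[, ord[seq_len(nMacro)], drop = FALSE])
  cl <- clusterMicrostates(V, nMacro, seed = seed)
  msm@macrostates <- cl$labels
  msm
}

#' Map MSM stationary weights onto frames
#'
#' Each frame inherits the equilibrium probability of its microstate
#' divided by the number of frames in that microstate, so the weights of
#' all frames in a state sum to the state's stationary probability.
#' Frames in states outside the active set get weight zero. Weights are
#' normalized to sum to 1.
#'
#' @param msm an \linkS4class{MSMResult}.
#' @param labels integer microstate labels of the frames (vector or list
#'   of vectors, concatenated in order).
#' @return numeric frame weights summing to 1.
#' @export
frameWeights <- function(msm, labels) {
  lab <- unlist(.asTrajList(labels))
  w <- numeric(length(lab))
  for (s in seq_along(msm@states)) {
    sel <- lab == msm@states[s]
    if (any(sel)) w[sel] <- msm@stationary[s] / sum(sel)
  }
  w / sum(w)
}

#' Two-dimensional free-energy surface
#'
#' Bins the first two projected coordinates on a regular grid (80 x 80 by
#' default), accumulates the equilibrium frame weights per bin, and
#' converts to free energies \eqn{F = -k_B T \ln p} in units of
#' \eqn{k_B T}, min-shifted to zero. Empty bins are NA. The surface is
#' invariant under uniform rescaling of the weights.
#'
#' @param projections F x 2 (or wider; first two columns used) matrix.
#' @param weights per-frame weights (default uniform).
#' @param grid number of bins per axis.
#' @param temperature reference temperature (K), stored for unit
#'   conversions.
#' @param edges optional list(x, y) of bin edges overriding the data
#'   range.
#' @return a \linkS4class{FreeEnergySurface}.
#' @export
freeEnergySurface <- function(projections, weights = NULL, grid = 80,
                              temperature = 300, edges = NULL) {
  P <- as.matrix(projections)[, 1:2, drop = FALSE]
  n <- nrow(P)
  if (n == 0) stop("no projections supplied")
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n) stop("one weight per frame required")
  if (all(weights == 0)) stop("all weights are zero")
  weights <- weights / sum(weights)
  if (is.null(edges)) {
    pad <- function(r) r + c(-1, 1) * max(1e-9, diff(r) * 1e-9)
    edges <- list(x = seq(pad(range(P[, 1]))[1], pad(range(P[, 1]))[2],
                          length.out = grid + 1),
                  y = seq(pad(range(P[, 2]))[1], pad(range(P[, 2]))[2],
                          length.out = grid + 1))
  }
  ix <- findInterval(P[, 1], edges$x, rightmost.closed = TRUE)
  iy <- findInterval(P[, 2], edges$y, rightmost.closed = TRUE)
  nx <- length(edges$x) - 1; ny <- length(edges$y) - 1
  ok <- ix >= 1 & ix <= nx & iy >= 1 & iy <= ny
  p <- matrix(0, nx, ny)
  for (k in which(ok)) p[ix[k], iy[k]] <- p[ix[k], iy[k]] + weights[k]
  F_ <- -log(p)
  F_[!is.finite(F_)] <- NA
  F_ <- F_ - min(F_, na.rm = TRUE)
  new("FreeEnergySurface", xEdges = edges$x, yEdges = edges$y,
      energy = F_, temperature = temperature)
}

#' Per-macrostate equilibrium and RMSD statistics
#'
#' Computes the optimal-superposition (Kabsch) C-alpha RMSD of every frame
#' to a reference structure, identifies the native macrostate (the one
#' containing the conformation of minimum RMSD), and reports per
#' macrostate the equilibrium probability (sum of stationary weights of
#' its microstates) and the mean and minimum RMSD over its frames.
#'
#' @param msm an \linkS4class{MSMResult} with macrostates assigned (see
#'   \code{\link{assignMacrostates}}).
#' @param trajCoords F x n x 3 coordinate array (or list of arrays).
#' @param labels frame microstate labels matching \code{trajCoords}.
#' @param reference n x 3 reference coordinates sharing the bead set.
#' @param select optional indices restricting the RMSD to a subset of
#'   beads (e.g. a residue range).
#' @return list with \code{table} (data.frame: macrostate, probability,
#'   meanRMSD, minRMSD, nFrames), \code{native} (native macrostate id)
#'   and \code{rmsd} (per-frame RMSD).
#' @export
macrostateStats <- function(msm, trajCoords, labels, reference,
                            select = NULL) {
  if (length(msm@macrostates) == 0)
    stop("assign macrostates first (see assignMacrostates)")
  if (is.list(trajCoords)) {
    trajCoords <- do.call(abind3, trajCoords)
  }
  lab <- unlist(.asTrajList(labels))
  nF <- dim(trajCoords)[1]
  if (length(lab) != nF) stop("one label per frame required")
  ref <- as.matrix(reference)
  if (dim(trajCoords)[2] != nrow(ref))
    stop("reference and trajectory bead sets differ")
  if (!is.null(select)) ref2 <- ref[select, , drop = FALSE] else
    ref2 <- ref
  rmsd <- vapply(seq_len(nF), function(f) {
    x <- trajCoords[f, , ]
    if (!is.null(select)) x <- x[select, , drop = FALSE]
    kabschRMSD(ref2, x)
  }, 0)
  macroOfFrame <- rep(NA_integer_, nF)
  for (s in seq_along(msm@states))
    macroOfFrame[lab == msm@states[s]] <- msm@macrostates[s]
  nativeMacro <- macroOfFrame[which.min(rmsd)]
  tab <- do.call(rbind, lapply(sort(unique(msm@macrostates)),
                               function(m) {
    sel <- which(macroOfFrame == m)
    data.frame(macrostate = m,
               probability = sum(msm@stationary[msm@macrostates == m]),
               meanRMSD = mean(rmsd[sel]), minRMSD = min(rmsd[sel]),
               nFrames = length(sel))
  }))
  list(table = tab, native = nativeMacro, rmsd = rmsd)
}

# bind F x n x 3 arrays along the frame axis
abind3 <- function(...) {
  arrs <- list(...)
  n <- dim(arrs[[1]])[2]
  out <- array(0, c(sum(vapply(arrs, function(a) dim(a)[1], 0)), n, 3))
  at <- 0
  for (a in arrs) {
    out[at + seq_len(dim(a)[1]), , ] <- a
    at <- at + dim(a)[1]
  }
  out
}
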