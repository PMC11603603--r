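# run expr under a fixed RNG seed without disturbing the caller's stream
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()))
  } else on.exit(rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

.checkDomainMeta <- function(records) {
  need <- c("domain", "numResidues", "numNohAtoms", "helixFraction",
            "sheetFraction")
  miss <- !stats::complete.cases(records[, setdiff(need, "domain")])
  if (!all(need %in% names(records)))
    stop("domain records must have columns: ", paste(need, collapse = ", "))
  if (any(miss))
    stop("missing metadata for domain(s): ",
         paste(records$domain[miss], collapse = ", "))
}

#' Filter domain records for training
#'
#' Keeps domains that survive the three curation criteria: at most
#' \code{maxResidues} residues, at most \code{maxNohAtoms} heavy (noh)
#' atoms, and a combined helix + sheet fraction of at least
#' \code{minSSFraction}. All boundaries are inclusive for retention (a
#' domain is excluded only when it exceeds a size bound or falls below the
#' secondary-structure bound). Input order is preserved and the filter is
#' idempotent.
#'
#' @param records data.frame with columns \code{domain},
#'   \code{numResidues}, \code{numNohAtoms}, \code{helixFraction},
#'   \code{sheetFraction}.
#' @param maxResidues,maxNohAtoms,minSSFraction filter bounds.
#' @return the retained rows of \code{records}.
#' @export
filterDomains <- function(records, maxResidues = 150, maxNohAtoms = 1000,
                          minSSFraction = 0.5) {
  if (nrow(records) == 0) return(records)
  .checkDomainMeta(records)
  keep <- records$numResidues <= maxResidues &
    records$numNohAtoms <= maxNohAtoms &
    (records$helixFraction + records$sheetFraction) >= minSSFraction
  records[keep, , drop = FALSE]
}

#' Select domains for the scale-up evaluation set
#'
#' Band-pass analogue of \code{\link{filterDomains}}: keeps domains with
#' between \code{minResidues} and \code{maxResidues} residues (inclusive)
#' and combined helix + sheet fraction at least \code{minSSFraction}.
#'
#' @inheritParams filterDomains
#' @param minResidues lower residue bound (inclusive).
#' @return the retained rows of \code{records}.
#' @export
selectScaleup <- function(records, minResidues = 150, maxResidues = 250,
                          minSSFraction = 0.5) {
  if (nrow(records) == 0) return(records)
  .checkDomainMeta(records)
  keep <- records$numResidues >= minResidues &
    records$numResidues <= maxResidues &
    (records$helixFraction + records$sheetFraction) >= minSSFraction
  records[keep, , drop = FALSE]
}

#' Stride and split a CG dataset
#'
#' Subsamples every \code{stride}-th frame within each (domain,
#' temperature) trajectory, then assigns the pooled frames at random to
#' train/validation/test splits with the requested proportions. Splits are
#' disjoint, cover all strided frames, and are reproducible from
#' \code{seed}. With \code{byDomain = TRUE} whole domains (all their
#' frames) are assigned to one split instead of individual frames.
#'
#' @param dataset a \linkS4class{CGDataset}.
#' @param stride positive integer subsampling stride.
#' @param fractions length-3 numeric (train, validation, test) summing
#'   to 1.
#' @param seed integer RNG seed.
#' @param byDomain assign whole domains rather than frames.
#' @return list with \code{CGDataset} elements \code{train}, \code{val},
#'   \code{test}.
#' @export
strideAndSplit <- function(dataset, stride = 25,
                           fractions = c(0.90, 0.05, 0.05), seed = 1,
                           byDomain = FALSE) {
  if (nFrames(dataset) == 0) stop("dataset is empty")
  if (stride < 1 || stride != round(stride))
    stop("stride must be a positive integer")
  if (length(fractions) != 3 || any(fractions < 0) ||
      abs(sum(fractions) - 1) > 1e-8)
    stop("fractions must be three non-negative numbers summing to 1")
  traj <- paste(dataset@domain, dataset@temperature)
  keep <- unlist(lapply(split(seq_len(nFrames(dataset)), traj),
                        function(ix) ix[seq(1, length(ix), by = stride)]),
                 use.names = FALSE)
  keep <- sort(keep)
  strided <- dataset[keep]
  n <- nFrames(strided)
  assignSplit <- function(m) {
    cuts <- round(cumsum(fractions) * m)
    lab <- rep(3L, m)
    lab[seq_len(cuts[1])] <- 1L
    if (cuts[2] > cuts[1]) lab[(cuts[1] + 1):cuts[2]] <- 2L
    withSeed(seed, sample(lab))
  }
  if (byDomain) {
    doms <- unique(strided@domain)
    domLab <- assignSplit(length(doms))
    lab <- domLab[match(strided@domain, doms)]
  } else lab <- assignSplit(n)
  list(train = strided[lab == 1L], val = strided[lab == 2L],
       test = strided[lab == 3L])
}

#' Relative shape anisotropy
#'
#' Computes the relative shape anisotropy kappa^2 from the eigenvalues of
#' the gyration tensor: kappa^2 = 1 - 3 (l1 l2 + l2 l3 + l3 l1) /
#' (l1 + l2 + l3)^2. The statistic lies in [0, 1]; 0 for spherically
#' symmetric arrangements, 1 for collinear ones, and it is invariant under
#' rotation, translation and uniform scaling.
#'
#' @param coords n x 3 coordinate matrix, n >= 3.
#' @return scalar in [0, 1].
#' @export
computeRSA <- function(coords) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 3) stop("at least 3 points are required")
  xc <- sweep(coords, 2, colMeans(coords))
  S <- crossprod(xc) / nrow(xc)
  l <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  tr <- sum(l)
  if (tr <= 0) stop("degenerate coordinates: zero gyration radius")
  1 - 3 * (l[1] * l[2] + l[2] * l[3] + l[3] * l[1]) / tr^2
}

#' Write / read a CG dataset
#'
#' Serializes a \linkS4class{CGDataset} to a single self-describing file
#' (R serialization carrying a versioned hierarchical layout: per-frame
#' coordinate and force groups plus bead types and provenance metadata).
#' The round trip is lossless.
#'
#' @param dataset a \linkS4class{CGDataset}.
#' @param path file path.
#' @return \code{writeCGDataset} returns \code{path} invisibly;
#'   \code{readCGDataset} returns the \linkS4class{CGDataset}.
#' @export
writeCGDataset <- function(dataset, path) {
  stopifnot(is(dataset, "CGDataset"))
  obj <- list(format = "nohcg-cgdata-1",
              coords = lapply(dataset@frames, coords),
              forces = lapply(dataset@frames, forces),
              types = lapply(dataset@frames, beadTypes),
              domain = dataset@domain,
              temperature = dataset@temperature)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname writeCGDataset
#' @export
readCGDataset <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "nohcg-cgdata-1"))
    stop("not a CG dataset file: missing or wrong 'format' marker")
  for (g in c("coords", "forces", "types", "domain", "temperature"))
    if (is.null(obj[[g]]))
      stop("malformed CG dataset file: missing group '", g, "'")
  frames <- mapply(function(x, f, t) cgFrame(x, t, f),
                   obj$coords, obj$forces, obj$types, SIMPLIFY = FALSE)
  new("CGDataset", frames = frames, domain = obj$domain,
      temperature = obj$temperature)
}

#' Read an mdCATH-like fixture file into a CG dataset
#'
#' Loads a fixture written by \code{\link{writeFixtureDataset}} (per-domain
#' groups, per-temperature coordinate/force arrays, bead types and
#' metadata) and flattens it into a \linkS4class{CGDataset}, pooling all
#' temperatures with the temperature kept as per-frame metadata.
#'
#' @param path fixture file path.
#' @param domains optional character vector restricting which domain
#'   groups to load.
#' @return a \linkS4class{CGDataset}.
#' @export
readFixtureDataset <- function(path, domains = NULL) {
  obj <- .readFixtureRaw(path)
  ids <- names(obj$domains)
  if (!is.null(domains)) ids <- intersect(ids, domains)
  frames <- list(); dom <- character(); temp <- numeric()
  for (id in ids) {
    g <- obj$domains[[id]]
    for (tname in names(g$temperatures)) {
      arr <- g$temperatures[[tname]]
      nf <- dim(arr$coords)[1]
      for (f in seq_len(nf))
        frames[[length(frames) + 1L]] <-
          cgFrame(arr$coords[f, , ], g$types, arr$forces[f, , ])
      dom <- c(dom, rep(id, nf))
      temp <- c(temp, rep(as.numeric(tname), nf))
    }
  }
  new("CGDataset", frames = frames, domain = dom, temperature = temp)
}

.readFixtureRaw <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "nohcg-fixture-1"))
    stop("not a fixture dataset file: missing or wrong 'format' marker")
  for (id in names(obj$domains)) {
    g <- obj$domains[[id]]
    for (grp in c("meta", "types", "temperatures"))
      if (is.null(g[[grp]]))
        stop("malformed fixture: domain '", id, "' missing group '",
             grp, "'")
    for (tname in names(g$temperatures)) {
      arr <- g$temperatures[[tname]]
      if (is.null(arr$coords) || is.null(arr$forces))
        stop("malformed fixture: domain '", id, "', temperature ", tname,
             " missing coords/forces group")
    }
  }
  obj
}

#' Domain metadata table of a fixture file
#'
#' @param path fixture file path.
#' @return data.frame with one row per domain group (columns
#'   \code{domain}, \code{numResidues}, \code{numNohAtoms},
#'   \code{helixFraction}, \code{sheetFraction}, \code{numFrames}).
#' @export
domainSummary <- function(path) {
  obj <- .readFixtureRaw(path)
  if (length(obj$domains) == 0)
    return(data.frame(domain = character(), numResidues = numeric(),
                      numNohAtoms = numeric(), helixFraction = numeric(),
                      sheetFraction = numeric(), numFrames = numeric()))
  do.call(rbind, lapply(names(obj$domains), function(id) {
    g <- obj$domains[[id]]
    nf <- sum(vapply(g$temperatures, function(a) dim(a$coords)[1], 0))
    data.frame(domain = id, numResidues = g$meta$numResidues,
               numNohAtoms = g$meta$numNohAtoms,
               helixFraction = g$meta$helixFraction,
               sheetFraction = g$meta$sheetFraction, numFrames = nf)
  }))
}
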