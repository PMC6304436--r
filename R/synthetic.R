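#' Specify a spatial source
#'
#' A source is an isotropic Gaussian blob on the voxel grid: peak value
#' \code{amplitude} at \code{center}, standard deviation \code{radius}
#' voxels. Blobs stand in for the brain functional subnetworks that spatial
#' ICA recovers as independent components.
#'
#' @param sourceId integer id.
#' @param center numeric length-3 voxel coordinate (1-based, may be
#'   fractional).
#' @param radius positive blob sd in voxels.
#' @param amplitude peak signal value.
#' @return a list of class \code{sourceSpec}.
#' @export
sourceSpec <- function(sourceId, center, radius, amplitude = 1) {
  stopIfNot(length(center) == 3, "center must be a length-3 coordinate")
  stopIfNot(is.numeric(radius) && radius > 0,
    sprintf("source %s: radius must be > 0", sourceId))
  structure(
    list(sourceId = as.integer(sourceId), center = as.numeric(center),
      radius = as.numeric(radius), amplitude = as.numeric(amplitude)),
    class = "sourceSpec")
}

#' Specify a directed causal graph for VAR time courses
#'
#' \code{lagCoefficients[i, j, p]} is the influence of source j at lag p on
#' source i, so a directed edge j -> i lives in row i, column j. The
#' companion matrix of the system must have spectral radius < 1
#' (stationarity); self-lags on the diagonal are allowed.
#'
#' @param lagCoefficients numeric n x n x order array (a matrix is taken as
#'   order 1).
#' @param noiseSd per-source innovation sd (recycled to n).
#' @param innovations "laplace" (super-Gaussian, the default so that spatial
#'   ICA's non-Gaussianity requirement is met by the generated data) or
#'   "gaussian".
#' @return a list of class \code{causalGraph}.
#' @export
causalGraph <- function(lagCoefficients, noiseSd = 1,
                        innovations = c("laplace", "gaussian")) {
  innovations <- match.arg(innovations)
  if (is.matrix(lagCoefficients)) {
    lagCoefficients <- array(lagCoefficients, dim = c(dim(lagCoefficients), 1))
  }
  d <- dim(lagCoefficients)
  stopIfNot(length(d) == 3 && d[1] == d[2],
    "lagCoefficients must be an n x n x order array")
  n <- d[1]
  noiseSd <- rep_len(as.numeric(noiseSd), n)
  stopIfNot(all(noiseSd >= 0), "noiseSd must be >= 0")
  g <- structure(
    list(nSources = n, lagCoefficients = lagCoefficients,
      noiseSd = noiseSd, order = d[3], innovations = innovations),
    class = "causalGraph")
  r <- spectralRadius(g)
  if (r >= 1) {
    stop(sprintf(
      "causal graph is not stationary: companion spectral radius %.4f >= 1",
      r))
  }
  g
}

#' Spectral radius of a VAR system's companion matrix
#'
#' @param graph a \code{causalGraph}.
#' @return the largest eigenvalue modulus; < 1 means stationary.
#' @export
spectralRadius <- function(graph) {
  n <- graph$nSources
  p <- graph$order
  comp <- matrix(0, n * p, n * p)
  for (k in seq_len(p)) {
    comp[1:n, ((k - 1) * n + 1):(k * n)] <- graph$lagCoefficients[, , k]
  }
  if (p > 1) {
    comp[(n + 1):(n * p), 1:(n * (p - 1))] <- diag(n * (p - 1))
  }
  max(Mod(eigen(comp, only.values = TRUE)$values))
}

#' Render source specs as spatial maps
#'
#' Each source becomes an isotropic Gaussian blob on the grid, peak value =
#' amplitude at the center, sd = radius. Maps are returned in sourceId order
#' over an all-TRUE grid mask.
#'
#' @param specs list of \code{\link{sourceSpec}}.
#' @param gridShape integer length-3 grid dimensions.
#' @return a \linkS4class{SpatialMapSet}.
#' @export
makeSourceMaps <- function(specs, gridShape) {
  gridShape <- as.integer(gridShape)
  stopIfNot(length(gridShape) == 3, "gridShape must have 3 dimensions")
  specs <- specs[order(vapply(specs, `[[`, 1L, "sourceId"))]
  for (s in specs) {
    if (any(s$center < 1) || any(s$center > gridShape)) {
      stop(sprintf("source %d: center (%s) lies outside the grid",
        s$sourceId, paste(signif(s$center, 4), collapse = ", ")))
    }
  }
  mask <- array(TRUE, dim = gridShape)
  coords <- gridCoordinates(gridShape)
  vals <- vapply(specs, function(s) {
    d2 <- (coords[, 1] - s$center[1])^2 + (coords[, 2] - s$center[2])^2 +
      (coords[, 3] - s$center[3])^2
    s$amplitude * exp(-d2 / (2 * s$radius^2))
  }, numeric(prod(gridShape)))
  newMapSet(vals, mask,
    info = data.frame(sourceId = vapply(specs, `[[`, 1L, "sourceId")))
}

gridCoordinates <- function(gridShape) {
  as.matrix(expand.grid(x = seq_len(gridShape[1]), y = seq_len(gridShape[2]),
    z = seq_len(gridShape[3])))
}

#' Simulate VAR time courses from a causal graph
#'
#' Runs the vector-autoregressive recursion with independent innovations
#' (Laplace by default, rescaled to the requested sd), discards
#' \code{burnIn} initial samples, and returns the remaining series.
#' Deterministic given \code{seed}.
#'
#' @param graph a \code{\link{causalGraph}}.
#' @param nTimepoints samples to keep after burn-in.
#' @param burnIn initial samples to discard (>= 100).
#' @param seed integer RNG seed.
#' @return numeric nSources x nTimepoints matrix.
#' @export
simulateVarTimecourses <- function(graph, nTimepoints, burnIn = 200,
                                   seed = 1) {
  stopIfNot(inherits(graph, "causalGraph"), "graph must be a causalGraph")
  stopIfNot(burnIn >= 100, "burnIn must be >= 100")
  stopIfNot(nTimepoints >= 10 * graph$order,
    "nTimepoints must be >= 10 * VAR order")
  n <- graph$nSources
  p <- graph$order
  total <- nTimepoints + burnIn
  withSeed(seed, {
    innov <- if (graph$innovations == "laplace") {
      # difference of exponentials has sd scale*sqrt(2); rescale to noiseSd
      matrix(stats::rexp(n * total) - stats::rexp(n * total), n, total) *
        (graph$noiseSd / sqrt(2))
    } else {
      matrix(stats::rnorm(n * total), n, total) * graph$noiseSd
    }
    x <- matrix(0, n, total)
    A <- graph$lagCoefficients
    for (t in seq_len(total)) {
      acc <- innov[, t]
      for (k in seq_len(min(p, t - 1))) {
        acc <- acc + A[, , k] %*% x[, t - k]
      }
      x[, t] <- acc
    }
    x[, (burnIn + 1):total, drop = FALSE]
  })
}

#' Synthesize one subject's 4-D volume
#'
#' Builds the linear mixture data = sum_s map_s * timecourse_s + noise that
#' spatial ICA assumes. Blob centers are jittered by a per-source Gaussian
#' offset (sd \code{jitterSd} voxels) and amplitudes by a multiplicative
#' log-normal factor, mimicking inter-subject variability. The mask is the
#' union of blob supports (3 radii) dilated by 2 voxels, unless a shared
#' \code{mask} is supplied.
#'
#' @param specs list of \code{\link{sourceSpec}} (jitter applies to these).
#' @param gridShape integer length-3.
#' @param timecourses nSources x T matrix.
#' @param jitterSd spatial jitter sd in voxels.
#' @param ampJitterSdLog sdlog of the log-normal amplitude factor.
#' @param noiseSd Gaussian sensor noise sd.
#' @param seed integer RNG seed.
#' @param subjectId,groupLabel identifiers stored on the volume.
#' @param mask optional shared logical mask overriding the support union.
#' @return a \linkS4class{FmriVolume}; the jittered specs are attached as
#'   attribute \code{"jitteredSpecs"}.
#' @export
synthesizeSubject <- function(specs, gridShape, timecourses, jitterSd = 0,
                              ampJitterSdLog = 0, noiseSd = 0, seed = 1,
                              subjectId = "s1", groupLabel = "control",
                              mask = NULL) {
  gridShape <- as.integer(gridShape)
  nS <- length(specs)
  stopIfNot(nrow(timecourses) == nS,
    "specs and timecourses disagree on the number of sources")
  tlen <- ncol(timecourses)
  jit <- withSeed(seed, list(
    offsets = matrix(stats::rnorm(3 * nS, sd = jitterSd), nS, 3),
    ampFac = stats::rlnorm(nS, meanlog = 0, sdlog = ampJitterSdLog),
    noise = if (noiseSd > 0) {
      stats::rnorm(prod(gridShape) * tlen, sd = noiseSd)
    } else NULL))
  jspecs <- lapply(seq_len(nS), function(i) {
    s <- specs[[i]]
    ctr <- pmin(pmax(s$center + jit$offsets[i, ], 1), gridShape)
    sourceSpec(s$sourceId, ctr, s$radius, s$amplitude * jit$ampFac[i])
  })
  maps <- mapValues(makeSourceMaps(jspecs, gridShape))
  dataMat <- maps %*% timecourses
  if (!is.null(jit$noise)) dataMat <- dataMat + jit$noise
  if (is.null(mask)) mask <- supportMask(jspecs, gridShape)
  vol <- methods::new("FmriVolume",
    data = array(dataMat, dim = c(gridShape, tlen)),
    mask = mask, affine = diag(4),
    subjectId = subjectId, groupLabel = groupLabel)
  attr(vol, "jitteredSpecs") <- jspecs
  vol
}

# Union of blob supports (3 radii around each center) dilated by `dilate`
# voxels, i.e. balls of radius 3 r + dilate.
supportMask <- function(specs, gridShape, dilate = 2) {
  coords <- gridCoordinates(gridShape)
  inside <- rep(FALSE, nrow(coords))
  for (s in specs) {
    d2 <- (coords[, 1] - s$center[1])^2 + (coords[, 2] - s$center[2])^2 +
      (coords[, 3] - s$center[3])^2
    inside <- inside | d2 <= (3 * s$radius + dilate)^2
  }
  array(inside, dim = gridShape)
}

#' Specify a two-group synthetic cohort
#'
#' Collects everything \code{\link{synthesizeCohort}} needs: the grid, base
#' sources, base causal graph, the group differences (group B minus group A)
#' in source amplitudes and directed VAR edges, the jitter and noise levels,
#' and the master seed. Defaults describe a desk-scale resting-state study:
#' a 16 x 16 x 8 grid, five Gaussian-blob subnetworks, a stationary VAR(1)
#' with two baseline directed edges, 120 timepoints at TR 2 s.
#'
#' @param nSubjectsPerGroup subjects per group (> 0).
#' @param gridShape integer length-3.
#' @param sourceSpecs list of \code{\link{sourceSpec}}; default 5 blobs.
#' @param graph base \code{\link{causalGraph}} (group A).
#' @param nTimepoints number of volumes (>= 10 * VAR order).
#' @param trSeconds repetition time, recorded but not used numerically.
#' @param groupAmplitudeDelta per-source amplitude shift for group B.
#' @param groupEdgeDelta n x n x order array added to group B's
#'   lag coefficients (or NULL for none).
#' @param spatialJitterSd per-subject blob-center jitter sd (voxels).
#' @param ampJitterSdLog per-subject log-normal amplitude jitter sdlog.
#' @param sensorNoiseSd Gaussian sensor noise sd.
#' @param seed master seed.
#' @return a list of class \code{cohortSpec}.
#' @export
cohortSpec <- function(nSubjectsPerGroup = 10,
                       gridShape = c(16, 16, 8),
                       sourceSpecs = defaultSourceSpecs(gridShape),
                       graph = defaultCausalGraph(length(sourceSpecs)),
                       nTimepoints = 120,
                       trSeconds = 2,
                       groupAmplitudeDelta = rep(0, length(sourceSpecs)),
                       groupEdgeDelta = NULL,
                       spatialJitterSd = 0.5,
                       ampJitterSdLog = 0.1,
                       sensorNoiseSd = 0.25,
                       seed = 1) {
  stopIfNot(nSubjectsPerGroup >= 1,
    "nSubjectsPerGroup must be a positive integer")
  stopIfNot(nTimepoints >= 10 * graph$order,
    "nTimepoints must be >= 10 * VAR order")
  stopIfNot(spatialJitterSd >= 0 && ampJitterSdLog >= 0 && sensorNoiseSd >= 0,
    "jitter and noise sds must be >= 0")
  stopIfNot(length(groupAmplitudeDelta) == length(sourceSpecs),
    "groupAmplitudeDelta needs one entry per source")
  structure(as.list(environment()), class = "cohortSpec")
}

#' Default five-blob source layout
#'
#' Five blobs at fixed fractional positions of the grid (four corners of a
#' mid-depth square plus a center blob at a different depth), radius an
#' eighth of the first grid dimension. On the default 16 x 16 x 8 grid
#' this gives radius-2 blobs with centers at least ~5.7 voxels apart.
#'
#' @param gridShape integer length-3 (default 16 x 16 x 8).
#' @return list of \code{\link{sourceSpec}}.
#' @export
defaultSourceSpecs <- function(gridShape = c(16, 16, 8)) {
  frac <- rbind(
    c(0.25, 0.25, 0.375), c(0.8125, 0.25, 0.375), c(0.25, 0.8125, 0.75),
    c(0.8125, 0.8125, 0.75), c(0.53125, 0.53125, 0.5))
  lapply(seq_len(nrow(frac)), function(i) {
    sourceSpec(i, frac[i, ] * gridShape, radius = gridShape[1] / 8,
      amplitude = 1)
  })
}

#' Default baseline causal graph
#'
#' Self-lags 0.35 on every source plus directed edges 1 -> 2 and 3 -> 4 of
#' strength 0.3, unit-sd Laplace innovations. Stationary by construction.
#'
#' @param nSources number of sources (>= 2).
#' @return a \code{\link{causalGraph}}.
#' @export
defaultCausalGraph <- function(nSources = 5) {
  A1 <- matrix(0, nSources, nSources)
  diag(A1) <- 0.35
  if (nSources >= 2) A1[2, 1] <- 0.3
  if (nSources >= 4) A1[4, 3] <- 0.3
  causalGraph(array(A1, dim = c(nSources, nSources, 1)), noiseSd = 1,
    innovations = "laplace")
}

#' Cohort spec with strong planted group differences
#'
#' Adds amplitude shifts (+1.5 on sources 3 and 5) and three extra directed
#' VAR edges (2 -> 3, 4 -> 5, 5 -> 1) for group B, giving a cohort the
#' downstream classifier should separate cleanly.
#'
#' @param ... passed on to \code{\link{cohortSpec}}.
#' @return a \code{cohortSpec}.
#' @export
separatedCohortSpec <- function(...) {
  delta <- array(0, dim = c(5, 5, 1))
  delta[3, 2, 1] <- 0.5
  delta[5, 4, 1] <- 0.5
  delta[1, 5, 1] <- 0.45
  cohortSpec(
    groupAmplitudeDelta = c(0, 0, 1.5, 0, 1.5),
    groupEdgeDelta = delta, ...)
}

#' Synthesize a two-group cohort with ground truth
#'
#' Generates \code{2 * nSubjectsPerGroup} volumes on one shared mask. Group A
#' subjects use the base sources and graph; group B sources are shifted by
#' \code{groupAmplitudeDelta} and the VAR coefficients by
#' \code{groupEdgeDelta} (checked for stationarity). Age and sex nuisance
#' covariates are drawn with no effect on the data. The returned truth
#' bundle records the per-group source maps, graphs, and labels.
#'
#' @param spec a \code{\link{cohortSpec}}.
#' @return list with elements \code{volumes} (list of
#'   \linkS4class{FmriVolume}), \code{labels}, \code{age}, \code{sex},
#'   \code{mask}, and \code{truth}.
#' @export
synthesizeCohort <- function(spec) {
  stopIfNot(inherits(spec, "cohortSpec"), "spec must be a cohortSpec")
  nPer <- spec$nSubjectsPerGroup
  grid <- as.integer(spec$gridShape)
  specsA <- spec$sourceSpecs
  specsB <- lapply(seq_along(specsA), function(i) {
    s <- specsA[[i]]
    sourceSpec(s$sourceId, s$center, s$radius,
      s$amplitude + spec$groupAmplitudeDelta[i])
  })
  graphA <- spec$graph
  graphB <- if (is.null(spec$groupEdgeDelta)) graphA else {
    causalGraph(graphA$lagCoefficients + spec$groupEdgeDelta,
      noiseSd = graphA$noiseSd, innovations = graphA$innovations)
  }
  labels <- rep(c("control", "patient"), each = nPer)
  n <- 2L * nPer
  ids <- sprintf("sub%02d", seq_len(n))
  covs <- withSeed(deriveSeed(spec$seed, 77), list(
    age = round(stats::rnorm(n, mean = 67, sd = 9), 1),
    sex = stats::rbinom(n, 1, 0.5)))
  vols <- vector("list", n)
  jspecsAll <- vector("list", n)
  for (i in seq_len(n)) {
    grp <- labels[i]
    gs <- if (grp == "control") graphA else graphB
    ss <- if (grp == "control") specsA else specsB
    tc <- simulateVarTimecourses(gs, spec$nTimepoints,
      seed = deriveSeed(spec$seed, i, 1))
    vols[[i]] <- synthesizeSubject(ss, grid, tc,
      jitterSd = spec$spatialJitterSd,
      ampJitterSdLog = spec$ampJitterSdLog,
      noiseSd = spec$sensorNoiseSd,
      seed = deriveSeed(spec$seed, i, 2),
      subjectId = ids[i], groupLabel = grp)
    jspecsAll[[i]] <- attr(vols[[i]], "jitteredSpecs")
  }
  mask <- Reduce(`|`, lapply(vols, brainMask))
  vols <- lapply(vols, function(v) {
    methods::initialize(v, mask = mask)
  })
  list(
    volumes = vols, labels = labels, age = covs$age, sex = covs$sex,
    mask = mask,
    truth = list(
      sourceSpecs = list(control = specsA, patient = specsB),
      graphs = list(control = graphA, patient = graphB),
      sourceMaps = makeSourceMaps(specsA, grid),
      jitteredSpecs = jspecsAll,
      labels = labels, spec = spec))
}
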