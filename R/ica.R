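#' Construct a component-number range
#'
#' @param lower,upper,step integers; the settings are
#'   \code{seq(lower, upper, step)}.
#' @return a \linkS4class{ComponentRange}.
#' @export
componentRange <- function(lower, upper, step = 1L) {
  methods::new("ComponentRange", lower = as.integer(lower),
    upper = as.integer(upper), step = as.integer(step))
}

#' Estimate the component-number range by information criteria
#'
#' Computes AIC and MDL model-order estimates from the eigenvalue spectrum
#' of the time-by-time covariance of the masked data (voxels are the
#' samples, as in spatial ICA), then spans a range from the smaller to the
#' larger estimate: the lower bound is rounded down and the upper bound up
#' to a step grid, with the step chosen so that the range holds at most
#' \code{maxSettings} settings.
#'
#' Both criteria use the standard spherical-tail likelihood of the
#' eigenvalue spectrum under an i.i.d.-voxel assumption (no spatial
#' smoothness correction).
#'
#' @param volume a \linkS4class{FmriVolume}.
#' @param maxSettings cap on the number of settings (default 12).
#' @return a \linkS4class{ComponentRange} with attributes \code{aic} and
#'   \code{mdl} holding the raw order estimates.
#' @export
estimateComponentRange <- function(volume, maxSettings = 12L) {
  x <- maskedData(volume)          # T x V
  tn <- nrow(x)
  stopIfNot(tn > 2, "need more than 2 timepoints")
  xc <- x - rowMeans(x)
  if (max(abs(xc)) == 0) stop("degenerate (constant) data")
  lambda <- eigen(tcrossprod(xc) / (ncol(xc) - 1),
    symmetric = TRUE, only.values = TRUE)$values
  lambda <- pmax(lambda, .Machine$double.eps)
  nObs <- ncol(x)
  ks <- seq_len(tn - 2)
  crit <- vapply(ks, function(k) {
    tail <- lambda[(k + 1):tn]
    m <- tn - k
    # log of (geometric mean / arithmetic mean) of the tail eigenvalues
    logRatio <- mean(log(tail)) - log(mean(tail))
    ll <- nObs * m * logRatio
    nPar <- k * (2 * tn - k)
    c(aic = -2 * ll + 2 * nPar, mdl = -ll + 0.5 * nPar * log(nObs))
  }, c(aic = 0, mdl = 0))
  aicHat <- ks[which.min(crit["aic", ])]
  mdlHat <- ks[which.min(crit["mdl", ])]
  lo <- max(2L, min(aicHat, mdlHat))
  hi <- max(lo, aicHat, mdlHat)
  for (step in c(1L, 2L, 5L, 10L, 20L, 50L)) {
    lower <- max(2L, as.integer(floor(lo / step) * step))
    upper <- as.integer(ceiling(hi / step) * step)
    if (length(seq.int(lower, upper, by = step)) <= maxSettings) break
  }
  out <- componentRange(lower, upper, step)
  attr(out, "aic") <- aicHat
  attr(out, "mdl") <- mdlHat
  out
}

# T x V matrix of in-mask voxel time series (rows are timepoints).
maskedData <- function(volume) {
  d <- dim(volume@data)
  t(matrix(volume@data, prod(d[1:3]), d[4])[as.vector(volume@mask), ,
    drop = FALSE])
}

# Fixed-point (logcosh contrast, symmetric decorrelation) ICA on the
# spatial orientation: voxels are samples, timepoints are sensors. PCA
# whitening to n components precedes the fixed-point iteration.
fastIcaCore <- function(x, n, seed, tol = 1e-4, maxit = 1000L) {
  tn <- nrow(x)
  v <- ncol(x)
  xc <- x - rowMeans(x)
  eg <- eigen(tcrossprod(xc) / (v - 1), symmetric = TRUE)
  lam <- pmax(eg$values[seq_len(n)], .Machine$double.eps)
  K <- diag(1 / sqrt(lam), n) %*% t(eg$vectors[, seq_len(n), drop = FALSE])
  z <- K %*% xc                                    # n x V, whitened
  W <- withSeed(seed, matrix(stats::rnorm(n * n), n, n))
  W <- symDecorrelate(W)
  converged <- FALSE
  for (it in seq_len(maxit)) {
    wz <- W %*% z
    g <- tanh(wz)
    W1 <- g %*% t(z) / v - diag(rowMeans(1 - g^2), n) %*% W
    W1 <- symDecorrelate(W1)
    delta <- max(abs(abs(diag(W1 %*% t(W))) - 1))
    W <- W1
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  s <- W %*% z                                     # n x V sources (maps)
  mixing <- eg$vectors[, seq_len(n), drop = FALSE] %*%
    diag(sqrt(lam), n) %*% t(W)                    # T x n time courses
  for (k in seq_len(n)) {
    if (sampleSkewness(s[k, ]) < 0) {
      s[k, ] <- -s[k, ]
      mixing[, k] <- -mixing[, k]
    }
  }
  list(sources = s, mixing = mixing, converged = converged,
    iterations = it)
}

symDecorrelate <- function(w) {
  e <- eigen(tcrossprod(w), symmetric = TRUE)
  e$vectors %*% diag(1 / sqrt(pmax(e$values, .Machine$double.eps)),
    nrow(w)) %*% t(e$vectors) %*% w
}

#' One spatial ICA decomposition
#'
#' Runs PCA whitening to \code{nComponents} followed by fixed-point ICA
#' (logcosh contrast, symmetric decorrelation) on the masked data in the
#' spatial orientation (voxels are samples). Each component map is
#' sign-aligned so its skewness is nonnegative and then z-scored over the
#' mask; time courses are the matched mixing-matrix columns.
#'
#' @param volume a \linkS4class{FmriVolume}.
#' @param nComponents number of components (<= min(T - 1, masked voxels)).
#' @param seed integer RNG seed (initial unmixing matrix).
#' @param tol convergence tolerance (default 1e-4).
#' @param maxit maximum fixed-point iterations (default 1000). A run that
#'   does not converge is returned with \code{converged = FALSE} and a
#'   warning, never silently.
#' @return list with \code{maps} (a z-scored \linkS4class{SpatialMapSet}),
#'   \code{timecourses} (T x n matrix) and \code{converged}.
#' @export
runIcaOnce <- function(volume, nComponents, seed = 1, tol = 1e-4,
                       maxit = 1000L) {
  x <- maskedData(volume)
  nComponents <- as.integer(nComponents)
  limit <- min(nrow(x) - 1L, ncol(x))
  if (nComponents > limit) {
    stop(sprintf(
      "nComponents = %d exceeds min(timepoints - 1, masked voxels) = %d",
      nComponents, limit))
  }
  fit <- fastIcaCore(x, nComponents, seed = seed, tol = tol, maxit = maxit)
  if (!fit$converged) {
    warning(sprintf(
      "ICA did not converge within %d iterations (subject %s, n = %d)",
      maxit, volume@subjectId, nComponents))
  }
  maps <- apply(fit$sources, 1, zScore)             # V x n
  info <- data.frame(subject = volume@subjectId, run = 1L,
    component = seq_len(nComponents), nComponents = nComponents)
  list(maps = newMapSet(maps, volume@mask, info),
    timecourses = fit$mixing, converged = fit$converged)
}

#' Repeated spatial ICA restarts
#'
#' Runs \code{\link{runIcaOnce}} \code{nRuns} times with distinct derived
#' seeds and pools all maps and time courses into one
#' \linkS4class{RunSet}, the input to level-1 density-peaks clustering.
#'
#' @param volume a \linkS4class{FmriVolume}.
#' @param nComponents components per restart.
#' @param nRuns number of restarts (>= 2; the repeated-run design needs
#'   replicates to cluster).
#' @param seed master seed; per-run seeds are derived from it.
#' @param ... passed to \code{\link{runIcaOnce}}.
#' @return a \linkS4class{RunSet} with \code{nRuns * nComponents} maps.
#' @export
runIcaMulti <- function(volume, nComponents, nRuns = 10L, seed = 1, ...) {
  nRuns <- as.integer(nRuns)
  stopIfNot(nRuns >= 2,
    "nRuns must be >= 2: level-1 clustering needs repeated runs")
  fits <- lapply(seq_len(nRuns), function(r) {
    f <- runIcaOnce(volume, nComponents, seed = deriveSeed(seed, r), ...)
    f$maps@info$run <- r
    f
  })
  vals <- do.call(cbind, lapply(fits, function(f) mapValues(f$maps)))
  tcs <- do.call(cbind, lapply(fits, `[[`, "timecourses"))
  info <- do.call(rbind, lapply(fits, function(f) mapInfo(f$maps)))
  methods::new("RunSet",
    maps = newMapSet(vals, volume@mask, info),
    timecourses = tcs,
    subjectId = volume@subjectId,
    nComponents = as.integer(nComponents),
    nRuns = nRuns,
    converged = vapply(fits, `[[`, logical(1), "converged"))
}
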