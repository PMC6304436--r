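# Internal helpers shared across stages.

# Evaluate expr under a fixed RNG state, restoring the caller's state after.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Stable derived seeds; kept below 2^31 - 1 so they stay valid R integers.
deriveSeed <- function(seed, ...) {
  ks <- c(...)
  s <- as.double(seed) %% 2147483647
  for (k in ks) s <- (s * 69069 + as.double(k) * 2654435761) %% 2147483647
  as.integer(s)
}

# column-wise sd without the data.frame overhead of apply(..., sd)
colSds <- function(x) {
  n <- nrow(x)
  mu <- colMeans(x)
  sqrt(pmax(colSums(x^2) - n * mu^2, 0) / (n - 1))
}

sampleSkewness <- function(x) {
  mu <- mean(x)
  s <- stats::sd(x)
  if (s == 0) return(0)
  mean((x - mu)^3) / s^3
}

zScore <- function(x) {
  s <- stats::sd(x)
  if (s == 0) stop("cannot z-score a constant map")
  (x - mean(x)) / s
}

# Voxelwise one-sample t over member maps (columns):
# t = mean / sqrt((sd^2 + varFloor^2) / m). The variance floor (default
# 0.01: 1% of the unit scale of z-scored maps) keeps the statistic finite
# where sd = 0 and stops it amplifying numerical scatter between
# near-duplicate members (ICA restarts of one subject converge to the same
# optimum up to ~1e-3 per-voxel scatter): below the floor t is
# proportional to the mean map, above it the ordinary one-sample t is
# recovered (the floor shifts a t of magnitude ~5 by < 1e-3). Voxels at or
# below the floor are counted as capped.
tStatKernel <- function(members, varFloor = 0.01) {
  m <- ncol(members)
  if (m < 2) stop("a t-map needs at least 2 member maps")
  mu <- rowMeans(members)
  sdv <- sqrt(pmax(rowSums((members - mu)^2), 0) / (m - 1))
  t <- mu / sqrt((sdv^2 + varFloor^2) / m)
  list(t = t, nCapped = sum(sdv <= varFloor & mu != 0))
}

# Construct a SpatialMapSet from a values matrix and mask.
newMapSet <- function(values, mask, info = NULL) {
  values <- as.matrix(values)
  if (is.null(info)) {
    info <- data.frame(map = seq_len(ncol(values)))
  }
  methods::new("SpatialMapSet", values = values, mask = mask, info = info)
}

# Embed masked vector(s) back into the full grid (NA outside the mask).
unmaskMap <- function(values, mask, fill = 0) {
  out <- array(fill, dim = dim(mask))
  out[mask] <- values
  out
}

stopIfNot <- function(cond, msg) if (!cond) stop(msg, call. = FALSE)
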