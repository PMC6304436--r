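#' Pairwise correlation distance between maps
#'
#' d_ij = 1 - |r_ij| with r the Pearson correlation over masked voxels, so
#' the distance lies in [0, 1] and is blind to ICA sign flips.
#'
#' @param maps a \linkS4class{SpatialMapSet} (or plain voxels x maps
#'   matrix) with at least 2 maps.
#' @return symmetric distance matrix with zero diagonal.
#' @export
mapDistance <- function(maps) {
  v <- if (methods::is(maps, "SpatialMapSet")) mapValues(maps) else maps
  stopIfNot(ncol(v) >= 2, "need at least 2 maps")
  sds <- colSds(v)
  if (any(sds == 0)) {
    stop(sprintf("constant map (zero variance): map %d",
      which(sds == 0)[1]))
  }
  d <- 1 - abs(stats::cor(v))
  d[d < 0] <- 0
  diag(d) <- 0
  d
}

#' Density-peaks clustering of maps
#'
#' Implements clustering by fast search of density peaks: the local density
#' rho_i = sum_j exp(-(d_ij / d_c)^2) with d_c the \code{dcQuantile}
#' quantile of the off-diagonal distances, and delta_i the distance to the
#' nearest point of higher density (the global density peak gets the
#' maximum distance). The first K points ranked by the center score are the
#' cluster centers; every other point inherits the label of its nearest
#' higher-density neighbor (or of its nearest center, if
#' \code{assignment = "nearest_center"}). Ties break toward the lowest
#' index everywhere, making runs reproducible.
#'
#' @param distanceMatrix symmetric distances in [0, 1].
#' @param K number of centers (<= number of points). The pipeline default
#'   is K = nComponents + 10.
#' @param dcQuantile quantile defining the density kernel width d_c
#'   (default 0.02, the original algorithm's 1--2 percent guidance).
#' @param centerScore "gamma" ranks centers by rho * delta (default);
#'   "rho_then_delta" sorts by rho with delta as tie-breaker.
#' @param assignment "nearest_higher_density" (default) or
#'   "nearest_center".
#' @param duplicateTol distances at or below this value are treated as
#'   exact duplicates (set to 0). Repeated ICA restarts that converge to
#'   the same optimum differ only by the fixed-point tolerance, so
#'   distances at that scale carry no cluster structure; the default
#'   matches the ICA convergence tolerance (1e-4).
#' @return list with \code{labels} (1..K per point), \code{centers}
#'   (point indices), \code{rho}, \code{delta}, \code{gamma}, \code{dc}.
#' @export
densityPeaks <- function(distanceMatrix, K,
                         dcQuantile = 0.02,
                         centerScore = c("gamma", "rho_then_delta"),
                         assignment = c("nearest_higher_density",
                           "nearest_center"),
                         duplicateTol = 1e-4) {
  centerScore <- match.arg(centerScore)
  assignment <- match.arg(assignment)
  d <- as.matrix(distanceMatrix)
  d[d <= duplicateTol] <- 0
  n <- nrow(d)
  stopIfNot(K >= 1 && K <= n, "K must lie in [1, number of points]")
  stopIfNot(dcQuantile > 0 && dcQuantile < 1, "dcQuantile must be in (0,1)")
  off <- d[upper.tri(d)]
  dc <- stats::quantile(off, dcQuantile, names = FALSE)
  if (dc == 0) {
    pos <- off[off > 0]
    if (!length(pos)) stop("d_c = 0: all points identical")
    dc <- min(pos)   # quantile landed on duplicate points; smallest real gap
  }
  rho <- rowSums(exp(-(d / dc)^2)) - 1           # exclude self term
  # rank points by density, ties to the lowest index
  ord <- order(-rho, seq_len(n))
  delta <- numeric(n)
  nn <- integer(n)                               # nearest higher-density pt
  delta[ord[1]] <- max(d[ord[1], ])
  nn[ord[1]] <- ord[1]
  for (k in seq_len(n)[-1]) {
    i <- ord[k]
    higher <- ord[seq_len(k - 1)]
    j <- higher[which.min(d[i, higher])]
    delta[i] <- d[i, j]
    nn[i] <- j
  }
  gamma <- rho * delta
  centers <- switch(centerScore,
    gamma = order(-gamma, seq_len(n))[seq_len(K)],
    rho_then_delta = order(-rho, -delta, seq_len(n))[seq_len(K)])
  labels <- integer(n)
  labels[centers] <- seq_len(K)
  if (assignment == "nearest_center") {
    for (i in seq_len(n)) {
      if (labels[i] == 0) labels[i] <- labels[centers[which.min(d[i, centers])]]
    }
  } else {
    for (k in seq_len(n)) {                      # descending-density sweep
      i <- ord[k]
      if (labels[i] == 0) labels[i] <- labels[nn[i]]
    }
  }
  list(labels = labels, centers = centers, rho = rho, delta = delta,
    gamma = gamma, dc = dc)
}

#' One-sample t group map over a cluster of maps
#'
#' Voxelwise t = mean / (sd / sqrt(m)) across the m member maps. Voxels
#' with zero sd are capped at 1.01 times the largest finite |t| so maps
#' stay finite and serializable; the number of capped voxels is recorded.
#'
#' @param members a \linkS4class{SpatialMapSet} (or voxels x members
#'   matrix) with at least 2 members.
#' @param mask logical 3-D mask (taken from \code{members} when it is a
#'   \linkS4class{SpatialMapSet}).
#' @return a one-map \linkS4class{SpatialMapSet}; attribute
#'   \code{"nCapped"} counts sd = 0 voxels, \code{"nMembers"} the members.
#' @export
groupMap <- function(members, mask = NULL) {
  if (methods::is(members, "SpatialMapSet")) {
    mask <- brainMask(members)
    members <- mapValues(members)
  }
  res <- tStatKernel(members)
  out <- newMapSet(matrix(res$t, ncol = 1), mask,
    info = data.frame(kind = "group_map", nMembers = ncol(members)))
  attr(out, "nCapped") <- res$nCapped
  attr(out, "nMembers") <- ncol(members)
  out
}

#' Level-1 clustering of one subject's ICA restarts
#'
#' Pools the RunSet's maps, clusters them by density peaks with
#' K = nComponents + \code{kOffset}, and emits a one-sample t group map
#' (GM) for every non-singleton cluster. Singleton clusters are reported
#' but produce no GM.
#'
#' @param runset a \linkS4class{RunSet}.
#' @param kOffset K = nComponents + kOffset (default 10).
#' @param dcQuantile,centerScore,assignment passed to
#'   \code{\link{densityPeaks}}.
#' @return list with \code{gms} (a \linkS4class{SpatialMapSet}),
#'   \code{lineage} (per GM, the member map indices into the RunSet),
#'   \code{assignment} (the \code{\link{densityPeaks}} result) and
#'   \code{singletons}.
#' @export
level1GroupMaps <- function(runset, kOffset = 10L, dcQuantile = 0.02,
                            centerScore = "gamma",
                            assignment = "nearest_higher_density",
                            duplicateTol = 1e-4) {
  K <- min(runset@nComponents + as.integer(kOffset), nMaps(runset))
  d <- mapDistance(runset@maps)
  cl <- densityPeaks(d, K, dcQuantile = dcQuantile,
    centerScore = centerScore, assignment = assignment,
    duplicateTol = duplicateTol)
  sizes <- tabulate(cl$labels, nbins = K)
  keep <- which(sizes >= 2)
  vals <- mapValues(runset)
  gmList <- lapply(keep, function(k) {
    idx <- which(cl$labels == k)
    res <- tStatKernel(vals[, idx, drop = FALSE])
    list(t = res$t, members = idx, nCapped = res$nCapped)
  })
  gmVals <- if (length(gmList)) {
    vapply(gmList, `[[`, numeric(nrow(vals)), "t")
  } else matrix(numeric(0), nrow(vals), 0)
  info <- data.frame(
    subject = rep(runset@subjectId, length(keep)),
    gm = seq_along(keep),
    nMembers = sizes[keep])
  list(
    gms = newMapSet(gmVals, brainMask(runset), info),
    lineage = lapply(gmList, `[[`, "members"),
    assignment = cl,
    singletons = which(sizes == 1))
}
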