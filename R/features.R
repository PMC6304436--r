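#' Voxelwise group-difference t-map with covariates
#'
#' Fits value ~ group + age + sex at every voxel by ordinary least squares
#' and returns the t statistic for the group contrast (group B minus group
#' A) with df = n - 4, plus two-sided p-values. With constant covariates
#' the model collapses to the plain two-sample t-test. Subjects whose map
#' is missing (NA column) are dropped from the fit.
#'
#' @param maps voxels x subjects matrix (or \linkS4class{SpatialMapSet})
#'   of per-subject maps for one component.
#' @param group factor or character with exactly 2 levels; the contrast is
#'   second level minus first.
#' @param age,sex numeric covariates per subject (default constant 0,
#'   i.e. no covariate adjustment).
#' @return list with \code{t}, \code{p} (vectors over voxels), \code{df},
#'   and \code{n} subjects used.
#' @export
groupDifferenceMap <- function(maps, group, age = NULL, sex = NULL) {
  v <- if (methods::is(maps, "SpatialMapSet")) mapValues(maps) else {
    as.matrix(maps)
  }
  n0 <- ncol(v)
  if (is.null(age)) age <- rep(0, n0)
  if (is.null(sex)) sex <- rep(0, n0)
  keep <- !is.na(v[1, ])
  v <- v[, keep, drop = FALSE]
  group <- factor(group[keep])
  age <- as.numeric(age[keep])
  sex <- as.numeric(sex[keep])
  stopIfNot(nlevels(group) == 2, "both groups must be nonempty")
  n <- ncol(v)
  X <- cbind(1, as.numeric(group == levels(group)[2]), age, sex)
  # drop constant covariate columns (keeps the design full rank) but keep
  # the stated df = n - 4 convention only when all 4 columns survive
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    keepCols <- c(TRUE, TRUE, stats::sd(age) > 0, stats::sd(sex) > 0)
    X <- X[, keepCols, drop = FALSE]
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) stop("rank-deficient design")
  }
  p <- ncol(X)
  stopIfNot(n > p, "too few subjects for the covariate model")
  xtxInv <- chol2inv(qr.R(qrX))
  beta <- xtxInv %*% crossprod(X, t(v))           # p x voxels
  resid <- t(v) - X %*% beta
  df <- n - p
  sigma2 <- colSums(resid^2) / df
  se <- sqrt(sigma2 * xtxInv[2, 2])
  tt <- as.numeric(beta[2, ]) / se
  tt[se == 0] <- 0
  pv <- 2 * stats::pt(abs(tt), df, lower.tail = FALSE)
  list(t = tt, p = pv, df = df, n = n)
}

#' Threshold a p-map into an ROI mask
#'
#' Keeps voxels with p strictly below \code{alpha} (uncorrected, matching
#' the group-analysis convention used upstream). An empty mask is allowed
#' but flagged.
#'
#' @param pMap numeric vector of voxelwise p-values.
#' @param alpha significance level (default 0.05).
#' @return logical vector; attribute \code{"empty"} flags an empty ROI.
#' @export
makeRoiMask <- function(pMap, alpha = 0.05) {
  roi <- pMap < alpha
  attr(roi, "empty") <- !any(roi)
  roi
}

#' Scalar functional-connectivity feature of a subject's component map
#'
#' The mean z-value of the subject's reliable IC map over the ROI voxels
#' (\code{statistic = "mean"}) or the maximum |z| within the ROI
#' (\code{statistic = "max_abs"}). An empty ROI, or a missing subject map,
#' yields 0 with attribute \code{"flagged"} = TRUE.
#'
#' @param map numeric vector over the mask (the subject's z-scored
#'   reliable IC), possibly NA.
#' @param roi logical ROI vector from \code{\link{makeRoiMask}}.
#' @param statistic "mean" (default) or "max_abs".
#' @return numeric scalar with attribute \code{"flagged"}.
#' @export
icFeature <- function(map, roi, statistic = c("mean", "max_abs")) {
  statistic <- match.arg(statistic)
  if (!any(roi) || any(is.na(map))) {
    return(structure(0, flagged = TRUE))
  }
  val <- switch(statistic,
    mean = mean(map[roi]),
    max_abs = max(abs(map[roi])))
  structure(val, flagged = FALSE)
}

#' Fuse effective and functional connectivity into one feature matrix
#'
#' Copies the GCI off-diagonals and replaces the undefined diagonal with
#' the per-component IC features, yielding the finite m x m matrix the
#' classifier consumes.
#'
#' @param gmat m x m GCI matrix (NA diagonal).
#' @param icFeatures numeric length-m vector.
#' @return m x m numeric matrix, finite everywhere.
#' @export
fuseFeatures <- function(gmat, icFeatures) {
  m <- nrow(gmat)
  stopIfNot(length(icFeatures) == m,
    "icFeatures length must match the GCI matrix size")
  out <- gmat
  attr(out, "order") <- NULL
  diag(out) <- as.numeric(icFeatures)
  if (any(!is.finite(out))) {
    stop("undefined off-diagonal GCI survived fusion")
  }
  out
}
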