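#' Extract a component time course from a volume
#'
#' Regresses each volume frame onto the component map by least squares over
#' the masked voxels (one scalar per timepoint), then removes the mean.
#' This shares one code path between training and test subjects; the
#' mixing-matrix column from ICA is available as an alternative upstream.
#'
#' @param volume a \linkS4class{FmriVolume}.
#' @param map numeric vector over the volume's mask (e.g. a reliable IC).
#' @return zero-mean numeric vector of length T.
#' @export
extractTimecourse <- function(volume, map) {
  x <- maskedData(volume)                       # T x V
  stopIfNot(length(map) == ncol(x), "map and volume must share a mask")
  denom <- sum(map^2)
  if (denom == 0) stop("zero-variance map: cannot extract a time course")
  tc <- as.numeric(x %*% map) / denom
  tc - mean(tc)
}

# Lagged design matrix: rows t = P+1..T, columns x(t-1)..x(t-P).
lagDesign <- function(x, p) {
  tt <- length(x)
  sapply(seq_len(p), function(k) x[(p + 1 - k):(tt - k)])
}

#' Fit the restricted AR model of a time course
#'
#' Ordinary least squares for x(t) = sum_i alpha_i x(t - i) + e over
#' t = P+1..T (no intercept: inputs are zero-meaned).
#'
#' @param x zero-mean numeric time course.
#' @param p AR order P (>= 1).
#' @return list with \code{coefficients} (alpha_1..alpha_P), \code{rss},
#'   \code{residuals}, and \code{sigma2} = RSS / (T - P) (diagnostic
#'   divisor convention).
#' @export
fitArRestricted <- function(x, p = 1L) {
  p <- as.integer(p)
  tt <- length(x)
  stopIfNot(p >= 1, "AR order must be >= 1")
  stopIfNot(tt - p >= 2 * p + 2, "time course too short for this order")
  y <- x[(p + 1):tt]
  X <- lagDesign(x, p)
  fit <- stats::lm.fit(as.matrix(X), y)
  if (any(is.na(fit$coefficients))) {
    stop("singular design in the restricted AR fit")
  }
  rss <- sum(fit$residuals^2)
  if (rss == 0 && all(fit$coefficients == 0)) {
    stop("singular design: time course is identically zero")
  }
  list(coefficients = fit$coefficients, rss = rss,
    residuals = fit$residuals, sigma2 = rss / (tt - p), order = p)
}

#' Fit the augmented AR model with a second time course
#'
#' OLS for x(t) = sum_i alpha_i x(t-i) + sum_j beta_j y(t-j) + e over the
#' same sample window t = P+1..T as the restricted model.
#'
#' @param x,y zero-mean numeric time courses of equal length.
#' @param p AR order P.
#' @return list as \code{\link{fitArRestricted}} with
#'   \code{coefficients} = (alpha_1..alpha_P, beta_1..beta_P).
#' @export
fitArAugmented <- function(x, y, p = 1L) {
  p <- as.integer(p)
  tt <- length(x)
  stopIfNot(length(y) == tt, "time courses must have equal length")
  stopIfNot(tt - p >= 2 * p + 2, "time course too short for this order")
  X <- cbind(lagDesign(x, p), lagDesign(y, p))
  fit <- stats::lm.fit(as.matrix(X), x[(p + 1):tt])
  if (any(is.na(fit$coefficients))) {
    stop("singular design in the augmented AR fit")
  }
  rss <- sum(fit$residuals^2)
  list(coefficients = fit$coefficients, rss = rss,
    residuals = fit$residuals, sigma2 = rss / (tt - p), order = p)
}

#' Granger causality index from Y to X
#'
#' GCI_{Y->X} = 1 - var(e_XY) / var(e_X): one minus the ratio of the
#' augmented-model to the restricted-model residual variance. Both models
#' are fit by least squares on the same sample window and the ratio uses
#' the plain residual sums of squares, so 0 <= GCI < 1 structurally
#' (nested least squares cannot increase the RSS). A positive GCI means
#' the past of Y improves the prediction of X, i.e. Y Granger-causes X.
#'
#' @param x,y zero-mean numeric time courses.
#' @param p AR order P (default 1).
#' @return GCI in [0, 1); NA with a warning when the restricted residual
#'   variance is 0 (deterministic x).
#' @export
gci <- function(x, y, p = 1L) {
  restricted <- fitArRestricted(x, p)
  augmented <- fitArAugmented(x, y, p)
  if (restricted$rss == 0) {
    warning("restricted-model residual variance is 0; GCI undefined")
    return(NA_real_)
  }
  1 - augmented$rss / restricted$rss
}

#' Select the AR order by BIC
#'
#' Scores the restricted AR model of each series at orders
#' \code{1..maxOrder} by BIC and returns the order minimizing the summed
#' score across series.
#'
#' @param timecourses m x T matrix of zero-mean series.
#' @param maxOrder largest order to consider (default 5).
#' @return integer order.
#' @export
selectArOrder <- function(timecourses, maxOrder = 5L) {
  tt <- ncol(timecourses)
  orders <- seq_len(maxOrder)
  score <- vapply(orders, function(p) {
    sum(apply(timecourses, 1, function(x) {
      f <- fitArRestricted(x, p)
      n <- tt - p
      n * log(f$rss / n) + p * log(n)
    }))
  }, numeric(1))
  orders[which.min(score)]
}

#' Granger causality index matrix over component time courses
#'
#' Fills entry [x, y] with GCI_{Y->X} for every ordered pair of the m time
#' courses. The diagonal is NA: there is no meaningful directed
#' interaction from a component to itself (it is replaced by functional
#' connectivity features at fusion).
#'
#' @param timecourses m x T matrix (rows are zero-mean component time
#'   courses), m >= 2.
#' @param p AR order P (default 1), or "bic" to select it via
#'   \code{\link{selectArOrder}}.
#' @return m x m matrix, off-diagonals in [0, 1), diagonal NA. The AR
#'   order used is attached as attribute \code{"order"}.
#' @export
gciMatrix <- function(timecourses, p = 1L) {
  timecourses <- as.matrix(timecourses)
  m <- nrow(timecourses)
  stopIfNot(m >= 2, "need at least 2 time courses")
  if (identical(p, "bic")) p <- selectArOrder(timecourses)
  out <- matrix(NA_real_, m, m)
  for (xi in seq_len(m)) {
    for (yi in seq_len(m)) {
      if (xi != yi) {
        out[xi, yi] <- gci(timecourses[xi, ], timecourses[yi, ], p)
      }
    }
  }
  attr(out, "order") <- as.integer(p)
  out
}

#' Write a GCI matrix as TSV
#'
#' m x m tab-separated values with component ids as header and the literal
#' "NA" on the diagonal.
#'
#' @param gmat GCI matrix.
#' @param file output path.
#' @param ids component ids (default cluster1..m).
#' @return the path, invisibly.
#' @export
writeGciMatrix <- function(gmat, file, ids = NULL) {
  if (is.null(ids)) ids <- paste0("cluster", seq_len(nrow(gmat)))
  df <- as.data.frame(gmat)
  names(df) <- ids
  rownames(df) <- ids
  utils::write.table(df, file, sep = "\t", quote = FALSE,
    row.names = TRUE, col.names = NA)
  invisible(file)
}
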