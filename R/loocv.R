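#' Match a test subject's ICs to training reliable components
#'
#' For each training reliable component, selects the test IC minimizing
#' the Euclidean distance between z-maps, allowing a sign flip (the sign
#' minimizing the distance is kept). A test IC serving more than one
#' component, or a match distance above the \code{flagQuantile} of all
#' candidate distances, is flagged rather than rejected.
#'
#' @param testMaps a \linkS4class{RunSet} (its pooled z-maps are the
#'   candidates) or a voxels x maps matrix of z-scored test ICs.
#' @param referenceMaps voxels x m matrix of training reliable component
#'   maps (e.g. \code{clusterMeanMaps} of an \code{hpmIca} result).
#' @param flagQuantile distances above this quantile of all pairwise
#'   candidate distances raise a flag (default 0.95).
#' @return list with \code{indices} (chosen test IC per component),
#'   \code{signs}, \code{distances}, \code{maps} (voxels x m matrix of
#'   the selected sign-aligned test maps), \code{duplicated},
#'   \code{flagged}.
#' @export
matchTestIcs <- function(testMaps, referenceMaps, flagQuantile = 0.95) {
  cand <- if (methods::is(testMaps, "RunSet")) mapValues(testMaps) else {
    as.matrix(testMaps)
  }
  stopIfNot(ncol(cand) >= 1, "test run set is empty")
  ref <- as.matrix(referenceMaps)
  # z-maps: ||a - b||^2 = ||a||^2 + ||b||^2 - 2 a.b; sign-aligned distance
  # uses |a.b|
  cn <- colSums(cand^2)
  rn <- colSums(ref^2)
  dots <- crossprod(cand, ref)                 # candidates x components
  d2 <- outer(cn, rn, `+`) - 2 * abs(dots)
  d <- sqrt(pmax(d2, 0))
  idx <- apply(d, 2, which.min)
  dist <- d[cbind(idx, seq_len(ncol(ref)))]
  signs <- sign(dots[cbind(idx, seq_len(ncol(ref)))])
  signs[signs == 0] <- 1
  sel <- cand[, idx, drop = FALSE] *
    rep(signs, each = nrow(cand))
  thr <- stats::quantile(d, flagQuantile, names = FALSE)
  list(indices = idx, signs = signs, distances = dist, maps = sel,
    duplicated = duplicated(idx) | duplicated(idx, fromLast = TRUE),
    flagged = dist > thr)
}

# Feature matrix for one subject: GCI off-diagonals (AR order arOrder) over
# the component time courses + ROI-mean IC features on the diagonal.
# icMaps: voxels x m (NA column = subject missing that component).
subjectFeatureMatrix <- function(volume, icMaps, rois, arOrder = 1L,
                                 statistic = "mean") {
  m <- ncol(icMaps)
  missing <- apply(icMaps, 2, function(col) any(is.na(col)))
  tt <- dim(volume@data)[4]
  tcs <- matrix(0, m, tt)
  for (k in seq_len(m)) {
    if (!missing[k]) tcs[k, ] <- extractTimecourse(volume, icMaps[, k])
  }
  gmat <- matrix(0, m, m)
  for (xi in seq_len(m)) {
    for (yi in seq_len(m)) {
      if (xi == yi) next
      gmat[xi, yi] <- if (missing[xi] || missing[yi]) 0 else {
        # a duplicated test-IC match makes x and y collinear; treat the
        # undefined GCI as 0 rather than aborting the fold
        g <- tryCatch(suppressWarnings(gci(tcs[xi, ], tcs[yi, ],
          arOrder)), error = function(e) NA_real_)
        if (is.na(g)) 0 else g
      }
    }
  }
  feats <- vapply(seq_len(m), function(k) {
    as.numeric(icFeature(icMaps[, k], rois[[k]], statistic = statistic))
  }, numeric(1))
  diag(gmat) <- feats
  attr(gmat, "missing") <- missing
  gmat
}

#' Leave-one-out cross-validation of the full pipeline
#'
#' In every fold the held-out subject is excluded from 3LHPM-ICA cluster
#' retention, group statistics, ROI definition and classifier training;
#' it then passes through test-IC matching, feature extraction and
#' prediction. Per-subject ICA restarts and level-1 group maps are
#' subject-local and may be precomputed once and shared across folds via
#' \code{cache} (no cross-subject information flows through them).
#'
#' @param cohort list with \code{volumes}, \code{labels} (values
#'   "patient"/"control"), \code{age}, \code{sex} (as produced by
#'   \code{\link{synthesizeCohort}}).
#' @param config a \code{\link{pipelineConfig}}.
#' @param cache optional \code{subjectMapCache} over all subjects.
#' @param labels optional label override (e.g. a permutation for a null
#'   calibration); group statistics and training use these labels.
#' @return list with per-fold results, pooled \code{predictions},
#'   \code{accuracy}, \code{sensitivity} (recall on "patient"),
#'   \code{specificity} (recall on "control") and the confusion matrix.
#' @export
runLoocv <- function(cohort, config = pipelineConfig("desk"), cache = NULL,
                     labels = NULL) {
  volumes <- cohort$volumes
  n <- length(volumes)
  stopIfNot(n >= 4, "LOOCV needs at least 4 subjects")
  if (is.null(labels)) labels <- cohort$labels
  stopIfNot(all(labels %in% c("patient", "control")),
    "labels must be 'patient'/'control'")
  L <- configSettings(config)
  if (is.null(cache)) {
    cache <- precomputeSubjectMaps(volumes, L, nRuns = config$nRuns,
      kOffset = config$kOffset, dcQuantile = config$dcQuantile,
      seed = config$seed, tol = config$icaTol, maxit = config$icaMaxit)
  }
  folds <- vector("list", n)
  preds <- character(n)
  for (fold in seq_len(n)) {
    trainIdx <- setdiff(seq_len(n), fold)
    trainVols <- volumes[trainIdx]
    trainLab <- labels[trainIdx]
    hp <- hpmIca(trainVols, L,
      minOwnerFraction = config$minOwnerFraction,
      level3MinOwnerFraction = config$level3MinOwnerFraction,
      competeThreshold = config$competeThreshold,
      minAlpha = config$minAlpha,
      exclusions = config$exclusions,
      seed = config$seed, cache = cache)
    m <- length(hp$retained)
    if (m < 3) {
      stop(sprintf(
        "fold %d: only %d reliable component(s) retained; cannot build features",
        fold, m))
    }
    # per-training-subject stacked reliable IC maps: voxels x m per subject
    trainMaps <- lapply(seq_along(trainVols), function(si) {
      s <- hp$subjects[si]
      vapply(hp$reliableIC, function(mat) mat[, s], numeric(sum(hp$mask)))
    })
    # ROI per component from training subjects only
    rois <- lapply(seq_len(m), function(k) {
      compMaps <- vapply(trainMaps, function(mm) mm[, k],
        numeric(sum(hp$mask)))
      gt <- groupDifferenceMap(compMaps, trainLab,
        age = cohort$age[trainIdx], sex = cohort$sex[trainIdx])
      makeRoiMask(gt$p, alpha = config$alphaThreshold)
    })
    trainFeats <- lapply(seq_along(trainVols), function(si) {
      subjectFeatureMatrix(trainVols[[si]], trainMaps[[si]], rois,
        arOrder = config$arOrder, statistic = config$icStatistic)
    })
    net <- dagNetwork(m, seed = deriveSeed(config$seed, fold, 91),
      skip = config$skipConnection)
    tcfg <- trainConfig(epochs = config$epochs,
      batchSize = config$batchSize, initialLr = config$initialLr,
      lrDropFactor = config$lrDropFactor,
      lrDropPeriod = config$lrDropPeriod,
      seed = deriveSeed(config$seed, fold, 92))
    net <- trainNetwork(net, trainFeats, trainLab, tcfg)
    # held-out subject: pooled test ICs from its largest setting
    testEntry <- cache$entries[[volumes[[fold]]@subjectId]]
    testCand <- do.call(cbind, lapply(testEntry, function(e) {
      mapValues(e$runset)
    }))
    mt <- matchTestIcs(testCand, hp$clusterMeanMaps)
    testFeat <- subjectFeatureMatrix(volumes[[fold]], mt$maps, rois,
      arOrder = config$arOrder, statistic = config$icStatistic)
    pr <- predictNetwork(net, testFeat)
    preds[fold] <- pr$labels[1]
    folds[[fold]] <- list(
      heldOut = volumes[[fold]]@subjectId, trueLabel = labels[fold],
      predicted = pr$labels[1], probs = pr$probs[1, ],
      nRetained = m, retained = hp$retained,
      matchFlags = list(duplicated = mt$duplicated, flagged = mt$flagged))
  }
  truth <- labels
  confusion <- table(truth = truth, predicted = factor(preds,
    levels = c("patient", "control")))
  acc <- mean(preds == truth)
  sens <- mean(preds[truth == "patient"] == "patient")
  spec <- mean(preds[truth == "control"] == "control")
  list(folds = folds, predictions = preds, labels = truth,
    accuracy = acc, sensitivity = sens, specificity = spec,
    confusion = confusion)
}
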