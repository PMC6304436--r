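#' Precompute per-subject ICA restarts and level-1 group maps
#'
#' Runs \code{\link{runIcaMulti}} and \code{\link{level1GroupMaps}} for
#' every subject at every component-number setting. These computations are
#' strictly subject-local (they see one subject's data only), so the cache
#' can be shared across cross-validation folds without information leakage;
#' all cross-subject stages are recomputed per fold.
#'
#' @param volumes list of \linkS4class{FmriVolume}.
#' @param settings integer vector L of component numbers.
#' @param nRuns ICA restarts per setting (default 10).
#' @param kOffset level-1 K = n + kOffset (default 10).
#' @param dcQuantile density-peaks kernel quantile (default 0.02).
#' @param seed master seed; per-(subject, setting) seeds are derived.
#' @param tol,maxit passed to \code{\link{runIcaOnce}}.
#' @return list of class \code{subjectMapCache}.
#' @export
precomputeSubjectMaps <- function(volumes, settings, nRuns = 10L,
                                  kOffset = 10L, dcQuantile = 0.02,
                                  seed = 1, tol = 1e-4, maxit = 1000L) {
  subjects <- vapply(volumes, function(v) v@subjectId, character(1))
  entries <- lapply(seq_along(volumes), function(si) {
    perSetting <- lapply(seq_along(settings), function(li) {
      rs <- runIcaMulti(volumes[[si]], settings[li], nRuns = nRuns,
        seed = deriveSeed(seed, si, li), tol = tol, maxit = maxit)
      list(runset = rs,
        level1 = level1GroupMaps(rs, kOffset = kOffset,
          dcQuantile = dcQuantile))
    })
    names(perSetting) <- as.character(settings)
    perSetting
  })
  names(entries) <- subjects
  structure(list(settings = settings, subjects = subjects,
    entries = entries), class = "subjectMapCache")
}

#' Three-level hierarchical partner matching ICA
#'
#' Level 1 clusters each subject's pooled ICA restarts by density peaks and
#' emits group maps (GMs). Level 2 partner-matches the GMs across subjects
#' (per component-number setting) and emits cluster maps (CMs). Level 3
#' partner-matches the CMs across settings; spatially overlapping level-3
#' clusters compete and the one with the highest Cronbach's alpha survives.
#' Backward tracing through CMs -> GMs -> ICs then yields each subject's
#' reliable IC per retained cluster (the voxelwise mean of the subject's
#' contributing ICs, re-z-scored).
#'
#' @param volumes list of \linkS4class{FmriVolume} (>= 2 subjects).
#' @param settings integer vector L of component numbers (>= 2 settings).
#' @param nRuns,kOffset,dcQuantile,seed,tol,maxit see
#'   \code{\link{precomputeSubjectMaps}}.
#' @param minOwnerFraction level-2 threshold: fraction of subjects a
#'   cluster must span (default 0.75).
#' @param level3MinOwnerFraction level-3 threshold over settings (default
#'   0.5: a genuine network need not appear at every model order, e.g. at
#'   settings below the true source count).
#' @param competeThreshold Tanimoto overlap above which two level-3
#'   clusters compete for the alpha selection (default 0.5).
#' @param minAlpha reliability floor: competition winners with Cronbach's
#'   alpha below this are not retained (default 0.7, the conventional
#'   acceptable-reliability threshold; unstable restart-noise clusters
#'   score far below it, genuine components far above).
#' @param exclusions integer ids of retained clusters to drop (manual
#'   artifact exclusion list).
#' @param cache optional \code{subjectMapCache} from
#'   \code{\link{precomputeSubjectMaps}} covering these subjects.
#' @return list of class \code{hpmicaResult}: per-level registries,
#'   retained clusters with alphas and lineage, and \code{reliableIC}, a
#'   list (one entry per retained cluster) of voxels x subjects matrices
#'   (NA column where a subject contributed no IC).
#' @export
hpmIca <- function(volumes, settings, nRuns = 10L, kOffset = 10L,
                   dcQuantile = 0.02, minOwnerFraction = 0.75,
                   level3MinOwnerFraction = 0.5, competeThreshold = 0.5,
                   minAlpha = 0.7, exclusions = integer(0), seed = 1,
                   tol = 1e-4, maxit = 1000L, cache = NULL) {
  stopIfNot(length(volumes) >= 2, "need at least 2 subjects")
  stopIfNot(length(settings) >= 2, "need at least 2 component settings")
  subjects <- vapply(volumes, function(v) v@subjectId, character(1))
  if (is.null(cache)) {
    cache <- precomputeSubjectMaps(volumes, settings, nRuns = nRuns,
      kOffset = kOffset, dcQuantile = dcQuantile, seed = seed, tol = tol,
      maxit = maxit)
  } else {
    stopIfNot(all(subjects %in% cache$subjects),
      "cache does not cover all subjects")
    stopIfNot(all(as.character(settings) %in%
      as.character(cache$settings)), "cache does not cover all settings")
  }
  mask <- brainMask(volumes[[1]])

  # ---- level 2: match GMs across subjects, per setting -------------------
  level2 <- lapply(as.character(settings), function(l) {
    gmSets <- lapply(subjects, function(s) cache$entries[[s]][[l]]$level1$gms)
    names(gmSets) <- subjects
    clusters <- matchAcrossOwners(gmSets,
      minOwnerFraction = minOwnerFraction)
    cmVals <- vapply(clusters, function(cl) {
      memberVals <- vapply(seq_len(nrow(cl$members)), function(r) {
        mapValues(gmSets[[cl$members$owner[r]]])[, cl$members$mapIndex[r]]
      }, numeric(sum(mask)))
      tStatKernel(memberVals)$t
    }, numeric(sum(mask)))
    if (length(clusters) == 0) cmVals <- matrix(numeric(0), sum(mask), 0)
    list(clusters = clusters,
      cms = newMapSet(cmVals, mask,
        info = data.frame(
          setting = rep(as.integer(l), length(clusters)),
          cm = seq_along(clusters))))
  })
  names(level2) <- as.character(settings)

  # ---- level 3: match CMs across settings --------------------------------
  cmSets <- lapply(level2, `[[`, "cms")
  level3 <- matchAcrossOwners(cmSets,
    minOwnerFraction = level3MinOwnerFraction)

  # alpha per level-3 cluster, over its member CMs
  memberMapsOf <- function(cl) {
    vapply(seq_len(nrow(cl$members)), function(r) {
      mapValues(cmSets[[cl$members$owner[r]]])[, cl$members$mapIndex[r]]
    }, numeric(sum(mask)))
  }
  alphas <- vapply(level3, function(cl) {
    cronbachAlpha(memberMapsOf(cl))$alpha
  }, numeric(1))

  # competition: overlapping clusters fight, highest alpha survives
  nc <- length(level3)
  winners <- integer(0)
  if (nc > 0) {
    overlap <- diag(nc) > 0
    mm <- lapply(level3, memberMapsOf)
    if (nc > 1) {
      for (i in seq_len(nc - 1)) {
        for (j in (i + 1):nc) {
          overlap[i, j] <- overlap[j, i] <-
            max(tanimotoCross(mm[[i]], mm[[j]])) > competeThreshold
        }
      }
    }
    g <- igraph::graph_from_adjacency_matrix(overlap, mode = "undirected",
      diag = FALSE)
    grpIds <- igraph::components(g)$membership
    winners <- vapply(seq_len(max(grpIds)), function(gid) {
      cand <- which(grpIds == gid)
      rank <- order(!is.finite(alphas[cand]), -alphas[cand], cand)
      cand[rank[1]]
    }, integer(1))
    winners <- sort(winners)
    winners <- winners[is.finite(alphas[winners]) &
      alphas[winners] >= minAlpha]
  }
  retained <- as.integer(setdiff(winners, exclusions))

  # ---- backward tracing: retained clusters -> per-subject reliable ICs ---
  reliableIC <- lapply(retained, function(cid) {
    cl <- level3[[cid]]
    # gather every contributing IC per subject, across all member CMs
    contrib <- stats::setNames(vector("list", length(subjects)), subjects)
    for (r in seq_len(nrow(cl$members))) {
      l <- cl$members$owner[r]
      cmIdx <- cl$members$mapIndex[r]
      l2cl <- level2[[l]]$clusters[[cmIdx]]
      if (is.null(l2cl)) stop(sprintf(
        "broken lineage for retained cluster %d at setting %s", cid, l))
      for (rr in seq_len(nrow(l2cl$members))) {
        s <- l2cl$members$owner[rr]
        gmIdx <- l2cl$members$mapIndex[rr]
        entry <- cache$entries[[s]][[l]]
        icIdx <- entry$level1$lineage[[gmIdx]]
        if (is.null(icIdx)) stop(sprintf(
          "broken lineage for retained cluster %d (subject %s)", cid, s))
        contrib[[s]] <- cbind(contrib[[s]],
          mapValues(entry$runset)[, icIdx, drop = FALSE])
      }
    }
    perSubject <- matrix(NA_real_, sum(mask), length(subjects),
      dimnames = list(NULL, subjects))
    for (s in subjects) {
      if (!is.null(contrib[[s]])) {
        perSubject[, s] <- zScore(rowMeans(contrib[[s]]))
      }
    }
    perSubject
  })
  names(reliableIC) <- paste0("cluster", retained)

  # group-level reference map per retained cluster (mean reliable IC)
  clusterMeanMaps <- if (length(retained)) {
    vapply(reliableIC, function(m) {
      mu <- rowMeans(m, na.rm = TRUE)
      zScore(mu)
    }, numeric(sum(mask)))
  } else matrix(numeric(0), sum(mask), 0)

  structure(list(
    subjects = subjects, settings = settings, mask = mask,
    cache = cache, level2 = level2, level3 = level3, alphas = alphas,
    winners = winners, retained = retained, exclusions = exclusions,
    reliableIC = reliableIC,
    clusterMeanMaps = clusterMeanMaps), class = "hpmicaResult")
}

#' @export
print.hpmicaResult <- function(x, ...) {
  cat("3LHPM-ICA result:", length(x$subjects), "subjects, settings L = {",
    paste(x$settings, collapse = ", "), "}\n")
  cms <- vapply(x$level2, function(l) nMaps(l$cms), integer(1))
  cat("  CMs per setting:", paste(cms, collapse = ", "), "\n")
  cat("  level-3 clusters:", length(x$level3),
    " retained after competition/exclusion:", length(x$retained), "\n")
  if (length(x$retained)) {
    cat("  alphas of retained:",
      paste(signif(x$alphas[x$retained], 4), collapse = ", "), "\n")
  }
  invisible(x)
}
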