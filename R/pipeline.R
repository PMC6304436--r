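#' Pipeline configuration
#'
#' All tunable settings of the end-to-end workflow in one list. The
#' \code{"reference"} profile carries the reference configuration: component
#' numbers 20 to 130 in steps of 10, 10 ICA restarts, level-1 K = n + 10,
#' p < 0.05 uncorrected ROIs, and the 20-epoch / batch-20 / 0.01 learning
#' rate (x0.1 every 10 epochs) training schedule. The \code{"desk"}
#' profile keeps every methodological default but shrinks the component
#' range (L = {4, 6, 8}) and restart count (5) to suit the bundled synthetic
#' cohorts.
#'
#' @param profile "reference" or "desk".
#' @param ... named overrides of individual fields.
#' @return a list of class \code{pipelineConfig}.
#' @export
pipelineConfig <- function(profile = c("reference", "desk"), ...) {
  profile <- match.arg(profile)
  cfg <- list(
    componentRange = list(lower = 20L, upper = 130L, step = 10L),
    nRuns = 10L,
    kOffset = 10L,
    dcQuantile = 0.02,
    minOwnerFraction = 0.75,
    level3MinOwnerFraction = 0.5,
    competeThreshold = 0.5,
    minAlpha = 0.7,
    alphaThreshold = 0.05,
    arOrder = 1L,
    icStatistic = "mean",
    skipConnection = TRUE,
    epochs = 20L,
    batchSize = 20L,
    initialLr = 0.01,
    lrDropFactor = 0.1,
    lrDropPeriod = 10L,
    icaTol = 1e-4,
    icaMaxit = 1000L,
    exclusions = integer(0),
    seed = 1L,
    profile = profile)
  if (profile == "desk") {
    cfg$componentRange <- list(lower = 4L, upper = 8L, step = 2L)
    cfg$nRuns <- 5L
    # batch 20 on ~20-subject cohorts means one update per epoch; batch 5
    # restores the ~3 updates/epoch of the reference protocol (67 / 20)
    cfg$batchSize <- 5L
  }
  overrides <- list(...)
  for (nm in names(overrides)) {
    stopIfNot(nm %in% names(cfg), sprintf("unknown config field '%s'", nm))
    cfg[[nm]] <- overrides[[nm]]
  }
  structure(cfg, class = "pipelineConfig")
}

#' Component settings L of a configuration
#' @param config a \code{\link{pipelineConfig}}.
#' @return integer vector.
#' @export
configSettings <- function(config) {
  r <- config$componentRange
  seq.int(r$lower, r$upper, by = r$step)
}

#' Validate a pipeline configuration
#'
#' Schema and cross-field checks; never silent.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @return list with \code{valid} (logical) and \code{messages}
#'   (character vector of problems, empty when valid).
#' @export
validateConfig <- function(config) {
  msgs <- character(0)
  chk <- function(cond, msg) if (!isTRUE(cond)) msgs <<- c(msgs, msg)
  r <- config$componentRange
  chk(is.list(r) && all(c("lower", "upper", "step") %in% names(r)),
    "componentRange must have lower/upper/step")
  if (is.list(r) && all(c("lower", "upper", "step") %in% names(r))) {
    chk(r$step >= 1, "componentRange step must be >= 1")
    chk(r$lower >= 2, "componentRange lower must be >= 2")
    chk(r$lower <= r$upper, "componentRange lower must be <= upper")
  }
  chk(config$nRuns >= 2, "nRuns must be >= 2 (repeated-run clustering)")
  chk(config$kOffset >= 0, "kOffset must be >= 0")
  chk(config$dcQuantile > 0 && config$dcQuantile < 1,
    "dcQuantile must lie in (0, 1)")
  chk(config$minOwnerFraction > 0 && config$minOwnerFraction <= 1,
    "minOwnerFraction must lie in (0, 1]")
  chk(config$level3MinOwnerFraction > 0 &&
    config$level3MinOwnerFraction <= 1,
    "level3MinOwnerFraction must lie in (0, 1]")
  chk(config$alphaThreshold > 0 && config$alphaThreshold <= 1,
    "alphaThreshold must lie in (0, 1]")
  chk(config$arOrder >= 1, "arOrder must be >= 1")
  chk(config$epochs >= 1, "epochs must be >= 1")
  chk(config$batchSize >= 1, "batchSize must be >= 1")
  chk(config$initialLr > 0, "initialLr must be > 0")
  chk(config$lrDropFactor > 0, "lrDropFactor must be > 0")
  chk(config$lrDropPeriod >= 1, "lrDropPeriod must be >= 1")
  list(valid = length(msgs) == 0, messages = msgs)
}

#' Read a pipeline configuration from YAML
#' @param file YAML path with top-level fields matching
#'   \code{\link{pipelineConfig}}.
#' @return a validated \code{pipelineConfig}.
#' @export
readPipelineConfig <- function(file) {
  raw <- yaml::read_yaml(file)
  profile <- if (is.null(raw$profile)) "reference" else raw$profile
  raw$profile <- NULL
  cfg <- do.call(pipelineConfig, c(list(profile = profile), raw))
  rep <- validateConfig(cfg)
  if (!rep$valid) {
    stop("invalid configuration:\n  ", paste(rep$messages, collapse = "\n  "))
  }
  cfg
}

configHash <- function(config) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(unclass(config), f, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(f))
}

#' Run the full pipeline on a cohort
#'
#' Executes the stages in order — 3LHPM-ICA (levels 1 to 3), reliable-IC
#' backtracing, per-subject GCI matrices, voxelwise group statistics and
#' ROI masks, feature fusion, and network training on all subjects — and
#' serializes every intermediate to \code{outDir}: cluster-map and
#' reliable-IC NIfTIs, GCI and feature TSVs, a cluster registry JSON and a
#' provenance record (seed, package version, config hash). A failing
#' stage halts with the stage name.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @param cohort a cohort list (see \code{\link{synthesizeCohort}} /
#'   \code{\link{readCohort}}).
#' @param outDir output directory.
#' @param cache optional \code{subjectMapCache}.
#' @return invisibly, a list with the \code{hpmIca} result, GCI matrices,
#'   ROI masks, per-subject feature matrices and the trained network.
#' @export
runPipeline <- function(config, cohort, outDir, cache = NULL) {
  rep <- validateConfig(config)
  if (!rep$valid) {
    stop("invalid configuration:\n  ", paste(rep$messages, collapse = "\n  "))
  }
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
        call. = FALSE)
    })
  }
  L <- configSettings(config)
  hp <- stage("3lhpm-ica", hpmIca(cohort$volumes, L,
    nRuns = config$nRuns, kOffset = config$kOffset,
    dcQuantile = config$dcQuantile,
    minOwnerFraction = config$minOwnerFraction,
    level3MinOwnerFraction = config$level3MinOwnerFraction,
    competeThreshold = config$competeThreshold,
    minAlpha = config$minAlpha,
    exclusions = config$exclusions, seed = config$seed,
    tol = config$icaTol, maxit = config$icaMaxit, cache = cache))
  m <- length(hp$retained)
  stopIfNot(m >= 2, "fewer than 2 reliable components retained")
  subjMaps <- lapply(seq_along(cohort$volumes), function(si) {
    s <- hp$subjects[si]
    vapply(hp$reliableIC, function(mat) mat[, s], numeric(sum(hp$mask)))
  })
  rois <- stage("group-statistics", lapply(seq_len(m), function(k) {
    compMaps <- vapply(subjMaps, function(mm) mm[, k],
      numeric(sum(hp$mask)))
    gt <- groupDifferenceMap(compMaps, cohort$labels, age = cohort$age,
      sex = cohort$sex)
    makeRoiMask(gt$p, alpha = config$alphaThreshold)
  }))
  feats <- stage("feature-fusion", lapply(seq_along(cohort$volumes),
    function(si) {
      subjectFeatureMatrix(cohort$volumes[[si]], subjMaps[[si]], rois,
        arOrder = config$arOrder, statistic = config$icStatistic)
    }))
  net <- stage("classifier-training", {
    net <- dagNetwork(m, seed = deriveSeed(config$seed, 991),
      skip = config$skipConnection)
    trainNetwork(net, feats, cohort$labels,
      trainConfig(epochs = config$epochs, batchSize = config$batchSize,
        initialLr = config$initialLr, lrDropFactor = config$lrDropFactor,
        lrDropPeriod = config$lrDropPeriod,
        seed = deriveSeed(config$seed, 992)))
  })
  stage("serialization", {
    for (l in names(hp$level2)) {
      if (nMaps(hp$level2[[l]]$cms) > 0) {
        writeMapSet(hp$level2[[l]]$cms,
          file.path(outDir, sprintf("cluster_maps_n%s.nii.gz", l)))
      }
    }
    for (ci in seq_along(hp$reliableIC)) {
      vals <- hp$reliableIC[[ci]]
      vals[is.na(vals)] <- 0
      writeMapSet(newMapSet(vals, hp$mask),
        file.path(outDir, sprintf("reliable_ic_%s.nii.gz",
          names(hp$reliableIC)[ci])))
    }
    for (si in seq_along(feats)) {
      utils::write.table(feats[[si]],
        file.path(outDir, sprintf("features_%s.tsv", hp$subjects[si])),
        sep = "\t", row.names = FALSE, col.names = FALSE)
    }
    registry <- list(
      settings = hp$settings,
      cmCounts = vapply(hp$level2, function(l) nMaps(l$cms), integer(1)),
      level3Clusters = length(hp$level3),
      alphas = hp$alphas,
      winners = hp$winners,
      retained = hp$retained,
      exclusions = config$exclusions)
    jsonlite::write_json(registry, file.path(outDir, "cluster_registry.json"),
      auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(list(
      seed = config$seed,
      packageVersion = as.character(utils::packageVersion("hpmica")),
      configHash = configHash(config),
      config = unclass(config)),
      file.path(outDir, "provenance.json"), auto_unbox = TRUE, digits = NA)
  })
  invisible(list(hpm = hp, rois = rois, features = feats, network = net,
    retained = hp$retained))
}
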