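test_that("source maps are Gaussian blobs with the stated peak", {
  specs <- list(sourceSpec(1, c(5, 5, 4), radius = 2, amplitude = 1))
  maps <- makeSourceMaps(specs, c(16, 16, 8))
  arr <- array(mapValues(maps)[, 1], c(16, 16, 8))
  expect_equal(arr[5, 5, 4], 1)
  expect_equal(max(arr), 1)
  # one-radius-away value follows the Gaussian profile
  expect_equal(arr[7, 5, 4], exp(-4 / (2 * 4)))
})

test_that("disjoint blobs are spatially uncorrelated", {
  specs <- list(
    sourceSpec(1, c(3, 3, 3), radius = 0.75, amplitude = 1),
    sourceSpec(2, c(13, 13, 6), radius = 0.75, amplitude = 2))
  v <- mapValues(makeSourceMaps(specs, c(16, 16, 8)))
  expect_lt(abs(cor(v[, 1], v[, 2])), 0.01)
})

test_that("invalid source specs are rejected with a named message", {
  expect_error(sourceSpec(3, c(1, 1, 1), radius = 0), "radius")
  expect_error(
    makeSourceMaps(list(sourceSpec(7, c(40, 1, 1), 1)), c(16, 16, 8)),
    "source 7")
})

test_that("VAR simulation matches closed-form autocorrelations", {
  # no lags: white noise, lag-1 autocorrelation ~ 0
  g0 <- causalGraph(array(0, c(2, 2, 1)), noiseSd = 1,
    innovations = "gaussian")
  x <- simulateVarTimecourses(g0, 10000, seed = 4)
  ac <- cor(x[1, -1], x[1, -10000])
  expect_lt(abs(ac), 0.05)
  expect_equal(sd(x[1, ]), 1, tolerance = 0.05)
  # single self-lag 0.9: AR(1) lag-1 autocorrelation = 0.9
  A <- array(0, c(2, 2, 1)); A[1, 1, 1] <- 0.9
  g1 <- causalGraph(A, innovations = "gaussian")
  y <- simulateVarTimecourses(g1, 10000, seed = 5)
  expect_equal(cor(y[1, -1], y[1, -10000]), 0.9, tolerance = 0.03)
})

test_that("VAR simulation is deterministic and innovation scaling holds", {
  g <- defaultCausalGraph(3)
  expect_identical(simulateVarTimecourses(g, 200, seed = 9),
    simulateVarTimecourses(g, 200, seed = 9))
  # laplace innovations still deliver the requested sd
  g2 <- causalGraph(array(0, c(1, 1, 1)), noiseSd = 2,
    innovations = "laplace")
  z <- simulateVarTimecourses(g2, 20000, seed = 2)
  expect_equal(sd(z), 2, tolerance = 0.06)
})

test_that("non-stationary graphs are rejected naming the spectral radius", {
  A <- array(0, c(2, 2, 1)); A[1, 1, 1] <- 1.05
  expect_error(causalGraph(A), "spectral radius 1.05")
})

test_that("subject synthesis is an exact mixture when noise-free", {
  specs <- twoBlobSpecs()
  g <- defaultCausalGraph(2)
  tc <- simulateVarTimecourses(g, 60, seed = 3)
  vol <- synthesizeSubject(specs, c(16, 16, 8), tc, seed = 5)
  x <- t(hpmica:::maskedData(vol))            # voxels x T
  # rank over masked voxels equals the number of sources
  expect_equal(qr(x)$rank, 2)
  # at the (unjittered) peak voxel the series equals the source time course
  idx <- array(seq_len(prod(c(16, 16, 8))), c(16, 16, 8))
  peak <- idx[4, 4, 4]
  maskIdx <- which(as.vector(brainMask(vol)))
  series <- x[match(peak, maskIdx), ]
  expect_gt(cor(series, tc[1, ]), 0.999)
  # reconstruction identity: data = maps %*% timecourses exactly
  maps <- mapValues(makeSourceMaps(attr(vol, "jitteredSpecs"),
    c(16, 16, 8)))[maskIdx, ]
  expect_lt(max(abs(x - maps %*% tc)), 1e-12)
})

test_that("subject synthesis is deterministic given the seed", {
  specs <- twoBlobSpecs()
  tc <- simulateVarTimecourses(defaultCausalGraph(2), 40, seed = 1)
  v1 <- synthesizeSubject(specs, c(16, 16, 8), tc, jitterSd = 0.5,
    ampJitterSdLog = 0.1, noiseSd = 0.3, seed = 8)
  v2 <- synthesizeSubject(specs, c(16, 16, 8), tc, jitterSd = 0.5,
    ampJitterSdLog = 0.1, noiseSd = 0.3, seed = 8)
  expect_identical(v1@data, v2@data)
  expect_identical(v1@mask, v2@mask)
})

test_that("cohort spec validation catches bad designs", {
  expect_error(cohortSpec(nSubjectsPerGroup = 0), "positive")
  expect_error(cohortSpec(nTimepoints = 5), "10 \\* VAR order")
  expect_error(cohortSpec(sensorNoiseSd = -1), ">= 0")
})

test_that("null cohorts put both groups in one distribution", {
  # with all deltas zero, a two-sample t on a source-amplitude feature
  # rejects at ~ the nominal rate
  reps <- 120
  pvals <- numeric(reps)
  for (r in seq_len(reps)) {
    spec <- cohortSpec(nSubjectsPerGroup = 5, gridShape = c(10, 10, 6),
      sourceSpecs = list(sourceSpec(1, c(5, 5, 3), 1.5)),
      graph = defaultCausalGraph(1), nTimepoints = 60, seed = 1000 + r)
    co <- synthesizeCohort(spec)
    peakIdx <- which.max(mapValues(co$truth$sourceMaps))
    maskIdx <- which(as.vector(co$mask))
    amp <- vapply(co$volumes, function(v) {
      sd(hpmica:::maskedData(v)[, match(peakIdx, maskIdx)])
    }, numeric(1))
    pvals[r] <- t.test(amp[co$labels == "patient"],
      amp[co$labels == "control"])$p.value
  }
  rate <- mean(pvals < 0.05)
  # binomial 95% band around 0.05 for 120 repetitions
  expect_lt(rate, 0.05 + 1.96 * sqrt(0.05 * 0.95 / reps))
})

test_that("planted amplitude differences are detectable downstream", {
  # delta = 1.5 on source 3, n = 10/group: ROI-feature two-sample t
  # rejects in > 90% of repetitions
  reps <- 25
  hits <- 0
  for (r in seq_len(reps)) {
    spec <- cohortSpec(nSubjectsPerGroup = 10,
      groupAmplitudeDelta = c(0, 0, 1.5, 0, 0), seed = 3000 + r)
    co <- synthesizeCohort(spec)
    src3 <- mapValues(co$truth$sourceMaps)[, 3]
    roiIdx <- which(src3[as.vector(co$mask)] > 0.5)
    amp <- vapply(co$volumes, function(v) {
      roi <- hpmica:::maskedData(v)[, roiIdx]
      sd(rowMeans(roi))
    }, numeric(1))
    p <- t.test(amp[co$labels == "patient"],
      amp[co$labels == "control"])$p.value
    hits <- hits + (p < 0.05)
  }
  expect_gt(hits / reps, 0.9)
})

test_that("cohort NIfTI round trip preserves data, mask and manifest", {
  co <- synthesizeCohort(cohortSpec(nSubjectsPerGroup = 2,
    gridShape = c(10, 10, 6), nTimepoints = 30, seed = 5))
  dir <- withr::local_tempdir()
  writeCohort(co, dir)
  expect_true(file.exists(file.path(dir, "ground_truth.json")))
  back <- readCohort(dir)
  expect_equal(length(back$volumes), 4)
  expect_equal(back$labels, co$labels)
  expect_equal(back$volumes[[1]]@data, co$volumes[[1]]@data,
    tolerance = 1e-6)
  expect_identical(back$mask, co$mask)
})
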