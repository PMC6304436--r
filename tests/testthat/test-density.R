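test_that("correlation distance is sign-blind and bounded", {
  m <- noiseMaps(500, 3, seed = 1)
  maps <- cbind(m[, 1], m[, 1], -m[, 1], m[, 2])
  d <- mapDistance(maps)
  expect_equal(d[1, 2], 0)
  expect_equal(d[1, 3], 0)          # negation: |r| = 1
  expect_true(all(d >= 0 & d <= 1))
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
  # far-apart disjoint blobs are nearly maximally distant
  specs <- list(sourceSpec(1, c(3, 3, 3), 0.75),
    sourceSpec(2, c(13, 13, 6), 0.75))
  v <- mapValues(makeSourceMaps(specs, c(16, 16, 8)))
  expect_gt(mapDistance(v)[1, 2], 0.99)
  expect_error(mapDistance(cbind(m[, 1], rep(1, 500))), "constant map")
})

test_that("density peaks recover well-separated planted clouds", {
  set.seed(42)
  centers <- noiseMaps(300, 3, seed = 7)
  pts <- do.call(cbind, lapply(1:3, function(k) {
    centers[, k] + matrix(rnorm(300 * 10, sd = 0.05), 300, 10)
  }))
  d <- mapDistance(pts)
  cl <- densityPeaks(d, 3)
  planted <- rep(1:3, each = 10)
  expect_equal(length(unique(cl$labels)), 3)
  # exact partition recovery up to label permutation
  expect_equal(unname(apply(table(planted, cl$labels) > 0, 1, sum)),
    c(1, 1, 1))
  agree <- outer(cl$labels, cl$labels, `==`) ==
    outer(planted, planted, `==`)
  expect_true(all(agree))
})

test_that("K = n gives the identity clustering and d_c = 0 is rejected", {
  pts <- noiseMaps(200, 5, seed = 3)
  d <- mapDistance(pts)
  cl <- densityPeaks(d, 5)
  expect_equal(sort(cl$centers), 1:5)
  expect_equal(length(unique(cl$labels)), 5)
  dup <- matrix(0, 4, 4)
  expect_error(densityPeaks(dup, 2), "identical")
})

test_that("gamma ranking reduces to rho or delta ranking when the other is flat", {
  rho <- c(5, 3, 8, 1)
  delta <- rep(2, 4)
  expect_equal(order(-(rho * delta)), order(-rho))
  rho2 <- rep(2, 4)
  delta2 <- c(0.1, 0.9, 0.4, 0.2)
  expect_equal(order(-(rho2 * delta2), 1:4), order(-delta2, 1:4))
})

test_that("group map matches the hand-computed one-sample t", {
  mask <- array(TRUE, c(2, 2, 1))
  members <- rbind(
    c(1, 2, 3, 2),      # t = 2 / (0.8165 / 2) = 4.899
    c(-3, 3, -3, 3),    # mean 0 -> t = 0
    c(5, 5, 5, 5),      # sd = 0 -> floored, finite
    c(0, 0, 0, 0))      # zero everywhere -> t = 0
  gm <- groupMap(members, mask)
  t <- mapValues(gm)[, 1]
  expect_equal(t[1], 4.899, tolerance = 1e-3)
  expect_equal(t[2], 0)
  expect_true(is.finite(t[3]) && t[3] > 100)
  expect_equal(t[4], 0)
  expect_equal(attr(gm, "nCapped"), 1)
  expect_error(groupMap(members[, 1, drop = FALSE], mask), "at least 2")
})

test_that("an all-identical nonzero cluster floors every nonzero voxel", {
  mask <- array(TRUE, c(4, 2, 1))
  one <- c(1.5, -2, 0.3, 4, -1, 2, 7, 0.1)
  gm <- groupMap(cbind(one, one, one), mask)
  expect_equal(attr(gm, "nCapped"), 8)
  t <- mapValues(gm)[, 1]
  expect_true(all(is.finite(t)))
  expect_gt(cor(t, one), 0.999)   # floored t stays proportional to the mean
})

test_that("level-1 clustering of restarts finds one GM per source", {
  specs <- twoBlobSpecs()
  vol <- mixtureVolume(specs, noiseSd = 0.2)
  rs <- runIcaMulti(vol, 2, nRuns = 10, seed = 4)
  l1 <- level1GroupMaps(rs, kOffset = 10)
  expect_equal(nMaps(l1$gms), 2)
  truth <- trueMapsFor(specs, vol)
  r <- abs(cor(mapValues(l1$gms), truth))
  expect_true(all(apply(r, 2, max) > 0.95))
  # lineage indexes valid member maps, >= 2 per GM
  expect_true(all(unlist(l1$lineage) %in% seq_len(nMaps(rs))))
  expect_true(all(lengths(l1$lineage) >= 2))
})

test_that("permuting input maps permutes labels but not the set of GMs", {
  set.seed(9)
  centers <- noiseMaps(200, 2, seed = 5)
  pts <- do.call(cbind, lapply(1:2, function(k) {
    centers[, k] + matrix(rnorm(200 * 5, sd = 0.05), 200, 5)
  }))
  perm <- sample(ncol(pts))
  cl1 <- densityPeaks(mapDistance(pts), 2)
  cl2 <- densityPeaks(mapDistance(pts[, perm]), 2)
  gm1 <- lapply(1:2, function(k) {
    sort(round(hpmica:::tStatKernel(pts[, cl1$labels == k,
      drop = FALSE])$t, 8))
  })
  gm2 <- lapply(1:2, function(k) {
    sort(round(hpmica:::tStatKernel(pts[, perm][, cl2$labels == k,
      drop = FALSE])$t, 8))
  })
  expect_true(setequal(gm1, gm2))
})
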