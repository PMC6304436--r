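test_that("Tanimoto similarity follows the generalized Jaccard formula", {
  expect_equal(tanimotoSimilarity(c(1, 1, 0), c(1, 0, 0)), 0.5)
  a <- c(0.3, 2, 0, 1)
  expect_equal(tanimotoSimilarity(a, a), 1)
  expect_equal(tanimotoSimilarity(c(1, 0, 0), c(0, 2, 3)), 0)
  # negative tails are rectified before scoring
  expect_equal(tanimotoSimilarity(c(1, -5, 0), c(1, 0, -2)), 1)
  expect_warning(z <- tanimotoSimilarity(c(-1, -2), c(0, -3)), "zero")
  expect_equal(z, 0)
})

test_that("bidirectional matching is a mutual argmax", {
  base <- noiseMaps(400, 4, seed = 2)
  shuffle <- c(3, 1, 4, 2)
  noisy <- base[, shuffle] + noiseMaps(400, 4, seed = 9) * 0.05
  pairs <- bidirectionalMatch(base, noisy)
  expect_equal(nrow(pairs), 4)
  expect_equal(pairs$j[order(pairs$i)], order(shuffle))
  # single maps with any nonzero similarity always pair
  one <- bidirectionalMatch(abs(base[, 1, drop = FALSE]),
    abs(base[, 2, drop = FALSE]))
  expect_equal(nrow(one), 1)
})

test_that("non-mutual argmax pairs are excluded", {
  # map 1's only option is b, but b prefers map 2: (1, b) must not appear
  m1 <- cbind(c(1, 0, 0, 0), c(1, 1, 1, 0))
  m2 <- cbind(c(1, 1, 1, 0.2))
  s <- sapply(1:2, function(i) tanimotoSimilarity(m1[, i], m2[, 1]))
  expect_equal(which.max(s), 2)    # b prefers map 2
  pairs <- bidirectionalMatch(m1, m2)
  expect_false(any(pairs$i == 1))
  expect_true(all(pairs$i == 2 & pairs$j == 1))
})

test_that("matching across owners forms one cluster per map", {
  base <- abs(noiseMaps(300, 3, seed = 4))
  cols <- lapply(1:4, function(i) base)
  names(cols) <- paste0("s", 1:4)
  cl <- matchAcrossOwners(cols)
  expect_length(cl, 3)
  for (c1 in cl) {
    expect_equal(nrow(c1$members), 4)
    expect_setequal(c1$members$owner, names(cols))
    expect_equal(c1$meanSimilarity, 1)
  }
})

test_that("owner-span threshold drops incomplete clusters", {
  base <- abs(noiseMaps(300, 2, seed = 6))
  cols <- list(s1 = base, s2 = base, s3 = base[, 1, drop = FALSE])
  full <- matchAcrossOwners(cols, minOwnerFraction = 1.0)
  expect_length(full, 1)            # map 2 is missing from one owner
  loose <- matchAcrossOwners(cols, minOwnerFraction = 0.6)
  expect_length(loose, 2)
})

test_that("matching is symmetric under collection reordering", {
  set.seed(8)
  base <- abs(noiseMaps(300, 3, seed = 12))
  cols <- lapply(1:3, function(i) base + abs(noiseMaps(300, 3, 20 + i)) * 0.1)
  names(cols) <- paste0("s", 1:3)
  cl1 <- matchAcrossOwners(cols)
  cl2 <- matchAcrossOwners(cols[c(2, 1, 3)])
  key <- function(cl) sort(vapply(cl, function(x) {
    paste(sort(paste(x$members$owner, x$members$mapIndex)), collapse = ";")
  }, character(1)))
  expect_equal(key(cl1), key(cl2))
})

test_that("Cronbach's alpha matches closed forms", {
  m <- noiseMaps(5000, 3, seed = 3)
  expect_equal(cronbachAlpha(cbind(m[, 1], m[, 1], m[, 1]))$alpha, 1)
  # independent items: alpha ~ 0
  a0 <- cronbachAlpha(noiseMaps(10000, 4, seed = 13))$alpha
  expect_lt(abs(a0), 0.05)
  # two items with exact sample correlation rho = 0.5 and equal variance:
  # Spearman-Brown gives alpha = 2 rho / (1 + rho) = 2/3
  x <- m[, 1]
  e <- stats::residuals(lm(m[, 2] ~ x))
  y <- 0.5 * sd(x) * scale(x)[, 1] + sqrt(0.75) * sd(x) * scale(e)[, 1]
  stopifnot(abs(cor(x, y) - 0.5) < 1e-10)
  expect_equal(cronbachAlpha(cbind(x, y))$alpha, 2 / 3, tolerance = 1e-6)
  # degenerate: zero total variance is flagged
  z <- cronbachAlpha(cbind(m[, 1], -m[, 1]))
  expect_true(z$flagged)
  expect_true(is.na(z$alpha))
})

test_that("alpha never exceeds 1 on random map sets", {
  for (k in c(2, 4, 7)) {
    a <- cronbachAlpha(noiseMaps(500, k, seed = 40 + k))$alpha
    expect_lte(a, 1)
  }
})

test_that("adding noise maps does not break strong existing pairs", {
  base <- abs(noiseMaps(300, 2, seed = 31))
  c1 <- base
  c2 <- base + abs(noiseMaps(300, 2, seed = 32)) * 0.05
  before <- bidirectionalMatch(c1, c2)
  c2big <- cbind(c2, abs(noiseMaps(300, 3, seed = 33)) * 0.2)
  after <- bidirectionalMatch(c1, c2big)
  for (r in seq_len(nrow(before))) {
    expect_true(any(after$i == before$i[r] & after$j == before$j[r]))
  }
})

test_that("full 3LHPM recovers planted sources and their correspondence", {
  co <- synthesizeCohort(cohortSpec(nSubjectsPerGroup = 2,
    sourceSpecs = separatedFiveSpecs(), seed = 77))
  hp <- suppressWarnings(hpmIca(co$volumes, c(5, 7), nRuns = 4, seed = 5))
  expect_gte(length(hp$retained), 4)
  truth <- mapValues(co$truth$sourceMaps)[as.vector(co$mask), ]
  matched <- integer(0)
  for (ric in hp$reliableIC) {
    ok <- colSums(is.na(ric)) == 0
    expect_gt(sum(ok), 0)
    r <- abs(cor(ric[, ok, drop = FALSE], truth))
    best <- which.max(colMeans(r))
    if (max(colMeans(r)) > 0.8) matched <- c(matched, best)
  }
  expect_gte(length(unique(matched)), 4)
  # alphas of retained clusters are high for genuine sources
  expect_true(any(hp$alphas[hp$retained] > 0.9))
})

test_that("manual exclusion removes a retained cluster", {
  co <- synthesizeCohort(cohortSpec(nSubjectsPerGroup = 2,
    sourceSpecs = twoBlobSpecs(), graph = defaultCausalGraph(2),
    seed = 21))
  cache <- suppressWarnings(precomputeSubjectMaps(co$volumes, c(2, 3),
    nRuns = 10, seed = 2))
  hp <- suppressWarnings(hpmIca(co$volumes, c(2, 3), seed = 2,
    cache = cache))
  expect_gte(length(hp$winners), 1)
  drop <- hp$winners[1]
  hp2 <- suppressWarnings(hpmIca(co$volumes, c(2, 3), seed = 2,
    cache = cache, exclusions = drop))
  expect_false(drop %in% hp2$retained)
  expect_setequal(hp2$retained, setdiff(hp$winners, drop))
})
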