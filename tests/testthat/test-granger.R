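test_that("time-course extraction inverts a noise-free mixture", {
  specs <- twoBlobSpecs()
  vol <- mixtureVolume(specs)
  trueTc <- simulateVarTimecourses(defaultCausalGraph(2), 120, seed = 11)
  truth <- trueMapsFor(attr(vol, "jitteredSpecs"), vol)
  tc1 <- extractTimecourse(vol, truth[, 1])
  expect_gt(cor(tc1, trueTc[1, ]), 0.999)
  expect_equal(mean(tc1), 0)
  # disjoint blob: orthogonal regressor picks up almost nothing of source 2
  expect_lt(abs(cor(tc1, trueTc[2, ])), 0.35)
  expect_error(extractTimecourse(vol, rep(0, nrow(truth))),
    "zero-variance")
})

test_that("restricted AR fits are consistent", {
  set.seed(3)
  x <- as.numeric(stats::filter(rnorm(10000), 0.9, method = "recursive"))
  x <- x - mean(x)
  f <- fitArRestricted(x, 1)
  expect_gt(f$coefficients[1], 0.87)
  expect_lt(f$coefficients[1], 0.93)
  w <- rnorm(10000); w <- w - mean(w)
  expect_lt(abs(fitArRestricted(w, 1)$coefficients[1]), 0.05)
  expect_error(fitArRestricted(rep(0, 200), 1), "singular")
})

test_that("augmented AR fits recover cross-lag coefficients", {
  set.seed(5)
  T <- 10000
  y <- rnorm(T)
  e <- rnorm(T)
  x <- as.numeric(stats::filter(0.8 * c(0, y[-T]) + e, 0.3,
    method = "recursive"))
  x <- x - mean(x); y <- y - mean(y)
  fa <- fitArAugmented(x, y, 1)
  expect_equal(unname(fa$coefficients[2]), 0.8, tolerance = 0.05)
  # independent y: no variance reduction
  y2 <- rnorm(T); y2 <- y2 - mean(y2)
  fr <- fitArRestricted(x, 1)
  fa2 <- fitArAugmented(x, y2, 1)
  expect_gt(fa2$rss / fr$rss, 0.99)
  expect_lte(fa2$rss / fr$rss, 1.0)
  # y = shifted copy of x: near-deterministic relation
  x3 <- rnorm(T); x3 <- x3 - mean(x3)
  fa3 <- fitArAugmented(x3, c(x3[-1], 0), 1)
  expect_lt(fa3$rss / sum(x3^2), 0.01)
})

test_that("GCI matches its population value and preserves direction", {
  # population oracle by brute-force long simulation (T = 1e6)
  set.seed(11)
  Tn <- 1e6
  yL <- rnorm(Tn); eL <- rnorm(Tn)
  xL <- as.numeric(stats::filter(0.8 * c(0, yL[-Tn]) + eL, 0.5,
    method = "recursive"))
  ar1 <- function(v) {
    n <- length(v)
    ph <- sum(v[-1] * v[-n]) / sum(v[-n]^2)
    sum((v[-1] - ph * v[-n])^2)
  }
  # oracle: lagged ls fit on the long series, done with base lm
  dfL <- data.frame(x = xL[-1], xl = xL[-Tn], yl = yL[-Tn])
  oracleGci <- 1 - sum(resid(lm(x ~ xl + yl - 1, dfL))^2) / ar1(xL)
  set.seed(21)
  Ts <- 10000
  y <- rnorm(Ts); e <- rnorm(Ts)
  x <- as.numeric(stats::filter(0.8 * c(0, y[-Ts]) + e, 0.5,
    method = "recursive"))
  x <- x - mean(x); y <- y - mean(y)
  expect_lt(abs(gci(x, y, 1) - oracleGci), 0.01)
  expect_lte(gci(y, x, 1), 0.01)
  # null: independent white noise
  set.seed(31)
  a <- rnorm(Ts); b <- rnorm(Ts)
  expect_lte(gci(a - mean(a), b - mean(b), 1), 0.01)
})

test_that("GCI is scale invariant and the matrix fills every ordered pair", {
  set.seed(7)
  tc <- simulateVarTimecourses(defaultCausalGraph(3), 2000, seed = 8)
  g1 <- gci(tc[2, ], tc[1, ], 1)
  g2 <- gci(tc[2, ] * 40, tc[1, ] / 7, 1)
  expect_equal(g1, g2, tolerance = 1e-12)
  gm <- gciMatrix(tc, 1)
  expect_equal(dim(gm), c(3, 3))
  expect_true(all(is.na(diag(gm))))
  off <- gm[row(gm) != col(gm)]
  expect_true(all(off >= 0 & off < 1))
})

test_that("a planted causal chain ranks above non-edges", {
  A <- array(0, c(3, 3, 1))
  diag(A[, , 1]) <- 0.3
  A1 <- A[, , 1]; A1[2, 1] <- 0.6; A1[3, 2] <- 0.6; A[, , 1] <- A1
  g <- causalGraph(A, innovations = "gaussian")
  tc <- simulateVarTimecourses(g, 10000, seed = 13)
  gm <- gciMatrix(tc, 1)
  edges <- c(gm[2, 1], gm[3, 2])
  nonEdges <- c(gm[1, 2], gm[1, 3], gm[2, 3], gm[3, 1])
  expect_gt(min(edges), max(nonEdges))
})

test_that("BIC order selection finds a higher-order system", {
  A <- array(0, c(1, 1, 2))
  A[1, 1, 2] <- 0.6            # pure lag-2 dependence
  g <- causalGraph(A, innovations = "gaussian")
  tc <- simulateVarTimecourses(g, 4000, seed = 17)
  expect_equal(selectArOrder(tc, maxOrder = 4), 2)
})

test_that("GCI matrix TSV has NA diagonal and ids", {
  tc <- simulateVarTimecourses(defaultCausalGraph(2), 500, seed = 3)
  gm <- gciMatrix(tc, 1)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeGciMatrix(gm, f, ids = c("icA", "icB"))
  txt <- readLines(f)
  expect_match(txt[1], "icA\ticB")
  back <- utils::read.delim(f, row.names = 1)
  expect_true(all(is.na(diag(as.matrix(back)))))
})
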