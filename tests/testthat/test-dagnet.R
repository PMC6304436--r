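test_that("forward pass yields normalized 2-vectors at the stated shapes", {
  net <- dagNetwork(24, seed = 3)
  x <- array(rnorm(24 * 24 * 1 * 3), c(24, 24, 1, 3))
  out <- predictNetwork(net, x)
  expect_equal(dim(out$probs), c(3, 2))
  expect_true(all(out$probs >= 0))
  expect_equal(unname(rowSums(out$probs)), rep(1, 3), tolerance = 1e-6)
})

test_that("all-zero weights give the symmetric prediction", {
  net <- dagNetwork(10, seed = 1)
  for (ln in names(net$params)) {
    for (pn in intersect(names(net$params[[ln]]),
      c("W", "b", "gamma", "beta"))) {
      net$params[[ln]][[pn]] <- net$params[[ln]][[pn]] * 0
    }
  }
  out <- predictNetwork(net, matrix(rnorm(100), 10, 10))
  expect_equal(unname(out$probs[1, ]), c(0.5, 0.5))
})

test_that("parameter count equals the closed-form layer arithmetic", {
  net <- dagNetwork(24, seed = 2)
  pool <- ((24 - 3) %/% 2 + 1)^2 * 32
  closedForm <- (5 * 5 * 1 * 16 + 16) +    # conv_1
    (3 * 3 * 16 * 32 + 32) +               # conv_2
    (3 * 3 * 32 * 32 + 32) +               # conv_3
    (1 * 1 * 16 * 32 + 32) +               # skipConv
    2 * 16 + 2 * 32 + 2 * 32 +             # batch-norm scale/shift
    (pool * 2 + 2)                         # fully connected
  expect_equal(networkParameterCount(net), closedForm)
  noSkip <- dagNetwork(24, seed = 2, skip = FALSE)
  expect_equal(networkParameterCount(noSkip),
    closedForm - (1 * 1 * 16 * 32 + 32))
})

test_that("analytic gradients agree with finite differences", {
  net <- dagNetwork(5, seed = 7)
  xs <- withr::with_seed(3, array(rnorm(5 * 5 * 1 * 4), c(5, 5, 1, 4)))
  ys <- c(1L, 2L, 1L, 2L)
  lossOf <- function(nn) {
    f <- hpmica:::networkForward(nn, xs, training = TRUE)
    -mean(log(f$probs[cbind(1:4, ys)]))
  }
  fw <- hpmica:::networkForward(net, xs, training = TRUE)
  gr <- hpmica:::networkBackward(net, fw, ys)
  eps <- 1e-5
  set.seed(9)
  for (ln in names(gr)) {
    for (pn in names(gr[[ln]])) {
      w <- net$params[[ln]][[pn]]
      for (ii in sample(length(w), min(3, length(w)))) {
        np <- net; np$params[[ln]][[pn]][ii] <- w[ii] + eps
        nm <- net; nm$params[[ln]][[pn]][ii] <- w[ii] - eps
        num <- (lossOf(np) - lossOf(nm)) / (2 * eps)
        ana <- gr[[ln]][[pn]][ii]
        expect_lt(abs(num - ana) / max(1e-6, abs(num) + abs(ana)), 0.01)
      }
    }
  }
})

test_that("training separates linearly separable features within 20 epochs", {
  set.seed(5)
  feats <- c(
    lapply(1:20, function(i) {
      m <- matrix(rnorm(25, 0, 0.5), 5, 5); diag(m) <- diag(m) + 3; m
    }),
    lapply(1:20, function(i) matrix(rnorm(25, 0, 0.5), 5, 5)))
  labs <- rep(c("patient", "control"), each = 20)
  net <- trainNetwork(dagNetwork(5, seed = 2), feats, labs,
    trainConfig(seed = 11))
  pr <- predictNetwork(net, feats)
  expect_equal(mean(pr$labels == labs), 1)
  expect_error(trainNetwork(dagNetwork(5, seed = 1), feats[1:20],
    labs[1:20], trainConfig(seed = 1)), "2 examples per class")
})

test_that("training is deterministic and follows the LR schedule", {
  set.seed(8)
  feats <- c(lapply(1:6, function(i) matrix(rnorm(25, 1), 5, 5)),
    lapply(1:6, function(i) matrix(rnorm(25, -1), 5, 5)))
  labs <- rep(c("patient", "control"), each = 6)
  cfg <- trainConfig(epochs = 12, seed = 4)
  n1 <- trainNetwork(dagNetwork(5, seed = 3), feats, labs, cfg)
  n2 <- trainNetwork(dagNetwork(5, seed = 3), feats, labs, cfg)
  expect_identical(n1$params, n2$params)
  expect_equal(n1$history$lr[1], 0.01)
  expect_equal(n1$history$lr[11], 0.001)  # dropped x0.1 after epoch 10
  expect_error(trainConfig(epochs = 0), "positive")
})

test_that("the skip-free ablation builds and runs", {
  net <- dagNetwork(6, seed = 4, skip = FALSE)
  out <- predictNetwork(net, matrix(rnorm(36), 6, 6))
  expect_equal(sum(out$probs), 1, tolerance = 1e-8)
  expect_null(net$params$skip)
})
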