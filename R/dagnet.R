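# Small DAG convolutional network for square connectivity-feature matrices.
#
# Main branch: input -> conv_1 (5x5, 16) -> BN -> ReLU -> conv_2 (3x3, 32)
# -> BN -> ReLU -> conv_3 (3x3, 32) -> BN -> [+ skipConv] -> ReLU ->
# avgpool (3x3, stride 2) -> fully connected (2) -> softmax.
# The shortcut taps the first post-ReLU activation through a 1x1, 32-filter
# convolution and merges by addition before the final ReLU. Stride-1 "same"
# padding keeps the skip and main shapes equal at the merge.
#
# Activations are (h, w, channels, batch) arrays. Convolutions run through
# an im2col matrix product; sizes here are tiny (m x m inputs with m equal
# to the number of retained components), so plain R linear algebra is fast.

pad4 <- function(x, p) {
  if (p == 0) return(x)
  d <- dim(x)
  out <- array(0, c(d[1] + 2 * p, d[2] + 2 * p, d[3], d[4]))
  out[p + seq_len(d[1]), p + seq_len(d[2]), , ] <- x
  out
}

im2col <- function(x, kh, kw, pad) {
  xp <- pad4(x, pad)
  d <- dim(x)
  oh <- d[1] + 2 * pad - kh + 1
  ow <- d[2] + 2 * pad - kw + 1
  cc <- d[3]
  n <- d[4]
  patches <- array(0, c(oh * ow, n, kh * kw * cc))
  k <- 0
  for (ci in seq_len(cc)) {
    for (dj in seq_len(kw)) {
      for (di in seq_len(kh)) {
        k <- k + 1
        sl <- xp[di:(di + oh - 1), dj:(dj + ow - 1), ci, , drop = FALSE]
        patches[, , k] <- matrix(sl, oh * ow, n)
      }
    }
  }
  list(mat = matrix(patches, oh * ow * n, kh * kw * cc), oh = oh, ow = ow)
}

col2im <- function(dmat, xdim, kh, kw, pad) {
  oh <- xdim[1] + 2 * pad - kh + 1
  ow <- xdim[2] + 2 * pad - kw + 1
  cc <- xdim[3]
  n <- xdim[4]
  dxp <- array(0, c(xdim[1] + 2 * pad, xdim[2] + 2 * pad, cc, n))
  dpat <- array(dmat, c(oh * ow, n, kh * kw * cc))
  k <- 0
  for (ci in seq_len(cc)) {
    for (dj in seq_len(kw)) {
      for (di in seq_len(kh)) {
        k <- k + 1
        dxp[di:(di + oh - 1), dj:(dj + ow - 1), ci, ] <-
          dxp[di:(di + oh - 1), dj:(dj + ow - 1), ci, ] +
          array(dpat[, , k], c(oh, ow, n))
      }
    }
  }
  if (pad == 0) dxp else {
    dxp[pad + seq_len(xdim[1]), pad + seq_len(xdim[2]), , , drop = FALSE]
  }
}

convForward <- function(x, layer) {
  ic <- im2col(x, layer$kh, layer$kw, layer$pad)
  out <- ic$mat %*% layer$W
  out <- sweep(out, 2, layer$b, `+`)
  n <- dim(x)[4]
  f <- ncol(layer$W)
  y <- aperm(array(out, c(ic$oh, ic$ow, n, f)), c(1, 2, 4, 3))
  list(y = y, cache = list(mat = ic$mat, xdim = dim(x)))
}

convBackward <- function(dy, layer, cache) {
  d <- dim(dy)
  dyMat <- matrix(aperm(dy, c(1, 2, 4, 3)), d[1] * d[2] * d[4], d[3])
  dW <- crossprod(cache$mat, dyMat)
  db <- colSums(dyMat)
  dmat <- dyMat %*% t(layer$W)
  dx <- col2im(dmat, cache$xdim, layer$kh, layer$kw, layer$pad)
  list(dx = dx, dW = dW, db = db)
}

bnForward <- function(x, layer, training, stats, eps = 1e-5) {
  d <- dim(x)
  xm <- matrix(aperm(x, c(1, 2, 4, 3)), d[1] * d[2] * d[4], d[3])
  if (training) {
    mu <- colMeans(xm)
    va <- colMeans(sweep(xm, 2, mu)^2)
  } else {
    mu <- stats$mean
    va <- stats$var
  }
  invstd <- 1 / sqrt(va + eps)
  xhat <- sweep(sweep(xm, 2, mu), 2, invstd, `*`)
  ym <- sweep(sweep(xhat, 2, layer$gamma, `*`), 2, layer$beta, `+`)
  y <- aperm(array(ym, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
  list(y = y, cache = list(xhat = xhat, invstd = invstd, d = d),
    batchStats = list(mean = mu, var = va))
}

bnBackward <- function(dy, layer, cache) {
  d <- cache$d
  nPer <- d[1] * d[2] * d[4]
  dyMat <- matrix(aperm(dy, c(1, 2, 4, 3)), nPer, d[3])
  dgamma <- colSums(dyMat * cache$xhat)
  dbeta <- colSums(dyMat)
  t1 <- sweep(dyMat, 2, dbeta / nPer)
  t2 <- sweep(cache$xhat, 2, dgamma / nPer, `*`)
  dxhat <- t1 - t2
  dxm <- sweep(dxhat, 2, layer$gamma * cache$invstd, `*`)
  dx <- aperm(array(dxm, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

avgPoolForward <- function(x, k = 3L, stride = 2L) {
  d <- dim(x)
  stopIfNot(d[1] >= k && d[2] >= k,
    "input too small for the average-pooling window")
  oh <- (d[1] - k) %/% stride + 1L
  ow <- (d[2] - k) %/% stride + 1L
  y <- array(0, c(oh, ow, d[3], d[4]))
  for (i in seq_len(oh)) {
    for (j in seq_len(ow)) {
      ri <- (i - 1) * stride + seq_len(k)
      rj <- (j - 1) * stride + seq_len(k)
      y[i, j, , ] <- apply(x[ri, rj, , , drop = FALSE], c(3, 4), mean)
    }
  }
  list(y = y, cache = list(d = d, k = k, stride = stride, oh = oh, ow = ow))
}

avgPoolBackward <- function(dy, cache) {
  dx <- array(0, cache$d)
  k <- cache$k
  for (i in seq_len(cache$oh)) {
    for (j in seq_len(cache$ow)) {
      ri <- (i - 1) * cache$stride + seq_len(k)
      rj <- (j - 1) * cache$stride + seq_len(k)
      add <- dy[i, j, , , drop = FALSE] / (k * k)
      for (a in seq_len(k)) {
        for (b in seq_len(k)) {
          dx[ri[a], rj[b], , ] <- dx[ri[a], rj[b], , ] +
            array(add, dim(add)[3:4])
        }
      }
    }
  }
  dx
}

newConvLayer <- function(kh, kw, cin, f, pad, seed) {
  W <- withSeed(seed, matrix(stats::rnorm(kh * kw * cin * f), kh * kw * cin,
    f)) * sqrt(2 / (kh * kw * cin))
  list(W = W, b = numeric(f), kh = kh, kw = kw, pad = pad)
}

#' Build the DAG convolutional network
#'
#' Constructs the network with the stated layer shapes: conv_1 5x5 with 16
#' filters, conv_2 and conv_3 3x3 with 32 filters, a 1x1 32-filter skip
#' convolution from the first post-ReLU activation merged by addition
#' before the final ReLU, batch normalization between every convolution
#' and its ReLU, 3x3 average pooling with stride 2, a 2-way fully
#' connected layer and softmax. With \code{skip = FALSE} the shortcut is
#' omitted, giving the plain sequential (LeNet-style) ablation.
#'
#' @param inputSize side length m of the m x m x 1 input.
#' @param seed integer seed for the (He) weight initialization.
#' @param skip include the shortcut connection (default TRUE).
#' @param filters integer length-3 filter counts (default 16, 32, 32).
#' @return a list of class \code{dagNetwork}.
#' @export
dagNetwork <- function(inputSize, seed = 1, skip = TRUE,
                       filters = c(16L, 32L, 32L)) {
  m <- as.integer(inputSize)
  stopIfNot(m >= 3, "input size must be at least 3 for 3x3 pooling")
  pside <- (m - 3L) %/% 2L + 1L
  fcIn <- pside * pside * filters[3]
  params <- list(
    conv1 = newConvLayer(5, 5, 1, filters[1], 2, deriveSeed(seed, 1)),
    bn1 = list(gamma = rep(1, filters[1]), beta = numeric(filters[1])),
    conv2 = newConvLayer(3, 3, filters[1], filters[2], 1,
      deriveSeed(seed, 2)),
    bn2 = list(gamma = rep(1, filters[2]), beta = numeric(filters[2])),
    conv3 = newConvLayer(3, 3, filters[2], filters[3], 1,
      deriveSeed(seed, 3)),
    bn3 = list(gamma = rep(1, filters[3]), beta = numeric(filters[3])),
    fc = list(
      W = withSeed(deriveSeed(seed, 5), matrix(stats::rnorm(fcIn * 2),
        fcIn, 2)) * sqrt(2 / fcIn),
      b = numeric(2))
  )
  if (skip) {
    params$skip <- newConvLayer(1, 1, filters[1], filters[3], 0,
      deriveSeed(seed, 4))
  }
  stats <- list(
    bn1 = list(mean = numeric(filters[1]), var = rep(1, filters[1])),
    bn2 = list(mean = numeric(filters[2]), var = rep(1, filters[2])),
    bn3 = list(mean = numeric(filters[3]), var = rep(1, filters[3])))
  structure(list(params = params, inputSize = m, skip = skip,
    filters = filters, poolSide = pside, bnStats = stats,
    classes = c("patient", "control"), trained = FALSE),
    class = "dagNetwork")
}

#' Trainable parameter count of the network
#' @param net a \code{\link{dagNetwork}}.
#' @return integer total of weights, biases and batch-norm scale/shift.
#' @export
networkParameterCount <- function(net) {
  sum(vapply(net$params, function(l) {
    sum(vapply(l[names(l) %in% c("W", "b", "gamma", "beta")], length,
      integer(1)))
  }, numeric(1)))
}

networkForward <- function(net, x, training = FALSE) {
  p <- net$params
  st <- net$bnStats
  c1 <- convForward(x, p$conv1)
  b1 <- bnForward(c1$y, p$bn1, training, st$bn1)
  r1 <- pmax(b1$y, 0)
  c2 <- convForward(r1, p$conv2)
  b2 <- bnForward(c2$y, p$bn2, training, st$bn2)
  r2 <- pmax(b2$y, 0)
  c3 <- convForward(r2, p$conv3)
  b3 <- bnForward(c3$y, p$bn3, training, st$bn3)
  merged <- b3$y
  sk <- NULL
  if (net$skip) {
    sk <- convForward(r1, p$skip)
    merged <- merged + sk$y
  }
  r3 <- pmax(merged, 0)
  pl <- avgPoolForward(r3)
  d <- dim(pl$y)
  flat <- t(matrix(pl$y, d[1] * d[2] * d[3], d[4]))
  logits <- sweep(flat %*% p$fc$W, 2, p$fc$b, `+`)
  mx <- apply(logits, 1, max)
  ex <- exp(logits - mx)
  probs <- ex / rowSums(ex)
  list(probs = probs, logits = logits,
    cache = list(c1 = c1, b1 = b1, r1 = r1, c2 = c2, b2 = b2, r2 = r2,
      c3 = c3, b3 = b3, sk = sk, merged = merged, r3 = r3, pl = pl,
      flat = flat))
}

networkBackward <- function(net, fw, y) {
  # y: integer class index (1 or 2) per sample; cross-entropy gradient
  p <- net$params
  ca <- fw$cache
  n <- nrow(fw$probs)
  dlogits <- fw$probs
  dlogits[cbind(seq_len(n), y)] <- dlogits[cbind(seq_len(n), y)] - 1
  dlogits <- dlogits / n
  grads <- list()
  grads$fc <- list(W = crossprod(ca$flat, dlogits), b = colSums(dlogits))
  dflat <- dlogits %*% t(p$fc$W)
  d <- dim(ca$pl$y)
  dpool <- array(t(dflat), d)
  dr3 <- avgPoolBackward(dpool, ca$pl$cache)
  dmerged <- dr3 * (ca$merged > 0)
  db3 <- bnBackward(dmerged, p$bn3, ca$b3$cache)
  grads$bn3 <- list(gamma = db3$dgamma, beta = db3$dbeta)
  dc3 <- convBackward(db3$dx, p$conv3, ca$c3$cache)
  grads$conv3 <- list(W = dc3$dW, b = dc3$db)
  dr2 <- dc3$dx * (ca$b2$y > 0)
  db2 <- bnBackward(dr2, p$bn2, ca$b2$cache)
  grads$bn2 <- list(gamma = db2$dgamma, beta = db2$dbeta)
  dc2 <- convBackward(db2$dx, p$conv2, ca$c2$cache)
  grads$conv2 <- list(W = dc2$dW, b = dc2$db)
  dr1 <- dc2$dx
  if (net$skip) {
    dskIn <- convBackward(dmerged, p$skip, ca$sk$cache)
    grads$skip <- list(W = dskIn$dW, b = dskIn$db)
    dr1 <- dr1 + dskIn$dx
  }
  dr1 <- dr1 * (ca$b1$y > 0)
  db1 <- bnBackward(dr1, p$bn1, ca$b1$cache)
  grads$bn1 <- list(gamma = db1$dgamma, beta = db1$dbeta)
  dc1 <- convBackward(db1$dx, p$conv1, ca$c1$cache)
  grads$conv1 <- list(W = dc1$dW, b = dc1$db)
  grads
}

#' Training configuration
#'
#' The stated schedule: 20 epochs, batch size 20, initial learning rate
#' 0.01 multiplied by 0.1 every 10 epochs; SGD with momentum 0.9 and
#' cross-entropy loss.
#'
#' @param epochs,batchSize,initialLr,lrDropFactor,lrDropPeriod,momentum
#'   scalars, all positive.
#' @param seed RNG seed for initialization and batch shuffling.
#' @return a list of class \code{trainConfig}.
#' @export
trainConfig <- function(epochs = 20L, batchSize = 20L, initialLr = 0.01,
                        lrDropFactor = 0.1, lrDropPeriod = 10L,
                        momentum = 0.9, seed = 1) {
  stopIfNot(epochs > 0 && batchSize > 0 && initialLr > 0 &&
    lrDropFactor > 0 && lrDropPeriod > 0,
    "all training settings must be positive")
  structure(list(epochs = as.integer(epochs),
    batchSize = as.integer(batchSize), initialLr = initialLr,
    lrDropFactor = lrDropFactor, lrDropPeriod = as.integer(lrDropPeriod),
    momentum = momentum, seed = seed), class = "trainConfig")
}

stackFeatures <- function(features) {
  # list of m x m matrices -> (m, m, 1, n) array
  m <- nrow(features[[1]])
  x <- array(0, c(m, m, 1, length(features)))
  for (i in seq_along(features)) x[, , 1, i] <- features[[i]]
  x
}

#' Train the DAG network
#'
#' Mini-batch stochastic gradient descent with momentum under the
#' configured learning-rate schedule. Batches are drawn by a seeded
#' shuffle each epoch; when fewer samples than the batch size are
#' available the whole set forms one batch, otherwise incomplete trailing
#' batches are dropped. After the last epoch the batch-normalization
#' statistics are finalized with one pass over the full training set.
#' Deterministic given the config seed.
#'
#' @param net a \code{\link{dagNetwork}}.
#' @param features list of m x m feature matrices (or an (m, m, 1, n)
#'   array).
#' @param labels character/factor labels; must contain both classes of
#'   \code{net$classes}.
#' @param cfg a \code{\link{trainConfig}}.
#' @return the trained network; element \code{history} records the loss
#'   per iteration and the learning rate per epoch.
#' @export
trainNetwork <- function(net, features, labels, cfg = trainConfig()) {
  x <- if (is.list(features)) stackFeatures(features) else features
  y <- match(as.character(labels), net$classes)
  stopIfNot(!any(is.na(y)), "labels must match the network classes")
  stopIfNot(length(unique(y)) == 2,
    "training needs at least 2 examples per class")
  n <- dim(x)[4]
  vel <- rapply(net$params, function(w) w * 0, how = "replace",
    classes = c("matrix", "numeric", "array"))
  losses <- numeric(0)
  lrs <- numeric(cfg$epochs)
  nBatches <- max(1L, n %/% cfg$batchSize)
  batchSize <- min(cfg$batchSize, n)
  for (epoch in seq_len(cfg$epochs)) {
    lr <- cfg$initialLr * cfg$lrDropFactor^((epoch - 1) %/% cfg$lrDropPeriod)
    lrs[epoch] <- lr
    perm <- withSeed(deriveSeed(cfg$seed, epoch), sample.int(n))
    for (bi in seq_len(nBatches)) {
      idx <- perm[(bi - 1) * batchSize + seq_len(batchSize)]
      xb <- x[, , , idx, drop = FALSE]
      yb <- y[idx]
      fw <- networkForward(net, xb, training = TRUE)
      loss <- -mean(log(pmax(fw$probs[cbind(seq_along(yb), yb)], 1e-12)))
      losses <- c(losses, loss)
      grads <- networkBackward(net, fw, yb)
      for (ln in names(grads)) {
        for (pn in names(grads[[ln]])) {
          g <- grads[[ln]][[pn]]
          vel[[ln]][[pn]] <- cfg$momentum * vel[[ln]][[pn]] - lr * g
          net$params[[ln]][[pn]] <- net$params[[ln]][[pn]] +
            vel[[ln]][[pn]]
        }
      }
    }
  }
  # finalize batch-norm statistics on the full training set
  fullFw <- networkForward(net, x, training = TRUE)
  net$bnStats$bn1 <- bnForward(fullFw$cache$c1$y, net$params$bn1, TRUE,
    NULL)$batchStats
  net$bnStats$bn2 <- bnForward(fullFw$cache$c2$y, net$params$bn2, TRUE,
    NULL)$batchStats
  net$bnStats$bn3 <- bnForward(fullFw$cache$c3$y, net$params$bn3, TRUE,
    NULL)$batchStats
  net$trained <- TRUE
  net$history <- list(loss = losses, lr = lrs)
  net
}

#' Predict class probabilities
#'
#' Forward pass with the stored batch-normalization statistics. The output
#' for each sample is a probability 2-vector over
#' \code{net$classes} (nonnegative, summing to 1).
#'
#' @param net a trained \code{\link{dagNetwork}}.
#' @param features list of m x m matrices, one matrix, or an
#'   (m, m, 1, n) array.
#' @return list with \code{probs} (n x 2 matrix, columns named by class)
#'   and \code{labels}.
#' @export
predictNetwork <- function(net, features) {
  if (is.matrix(features)) features <- list(features)
  x <- if (is.list(features)) stackFeatures(features) else features
  fw <- networkForward(net, x, training = FALSE)
  probs <- fw$probs
  colnames(probs) <- net$classes
  list(probs = probs,
    labels = net$classes[max.col(probs, ties.method = "first")])
}
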