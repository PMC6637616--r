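#' Architecture of the glaucoma classification network
#'
#' A compact AlexNet-style network: four convolutional layers followed by
#' three fully connected layers.  The first two convolutions are each
#' followed by local response normalization (LRN) and overlapping max
#' pooling; the fourth convolution is followed by max pooling; the first
#' two dense layers are followed by dropout; the last dense layer feeds a
#' softmax over the two classes.  Every convolutional and dense layer uses
#' the rectifier `f(x) = max(0, x)` except the output.
#'
#' The default geometry is conv1 `96 @ 11x11 stride 4`, conv2
#' `256 @ 5x5 pad 2`, conv3 `384 @ 3x3 pad 1`, conv4 `256 @ 3x3 pad 1`,
#' dense widths 1024, 1024; pooling window 3 with stride 2 (overlapping);
#' dropout probability 0.5.  Kernel counts and dense widths are
#' configurable — networks this size overfit small screening datasets, so
#' scaled-down widths are the norm for benchmarks.
#'
#' @param convKernels integer length-4, kernels per convolutional layer.
#' @param fcWidths integer length-2, widths of the hidden dense layers.
#' @param dropout dropout probability after each hidden dense layer.
#' @param poolWindow,poolStride max-pooling geometry; overlapping requires
#'   `poolStride < poolWindow`.
#' @param lrnWindow,lrnK,lrnAlpha,lrnBeta LRN parameters (AlexNet values).
#' @param nClasses number of output classes.
#' @return A validated list of class `NetSpec`.
#' @export
netSpec <- function(convKernels = c(96, 256, 384, 256),
                    fcWidths = c(1024, 1024), dropout = 0.5,
                    poolWindow = 3, poolStride = 2,
                    lrnWindow = 5, lrnK = 2, lrnAlpha = 1e-4,
                    lrnBeta = 0.75, nClasses = 2) {
  stopifnot(length(convKernels) == 4, all(convKernels >= 1),
            length(fcWidths) == 2, all(fcWidths >= 2),
            dropout >= 0, dropout < 1,
            poolStride >= 1, poolWindow > poolStride,
            nClasses >= 2)
  conv <- list(
    list(k = convKernels[1], size = 11, stride = 4, pad = 0,
         lrn = TRUE, pool = TRUE),
    list(k = convKernels[2], size = 5, stride = 1, pad = 2,
         lrn = TRUE, pool = TRUE),
    list(k = convKernels[3], size = 3, stride = 1, pad = 1,
         lrn = FALSE, pool = FALSE),
    list(k = convKernels[4], size = 3, stride = 1, pad = 1,
         lrn = FALSE, pool = TRUE))
  structure(list(conv = conv, fcWidths = as.integer(fcWidths),
                 dropout = dropout,
                 pool = list(p = as.integer(poolWindow),
                             s = as.integer(poolStride)),
                 lrn = list(n = as.integer(lrnWindow), k = lrnK,
                            alpha = lrnAlpha, beta = lrnBeta),
                 nClasses = as.integer(nClasses)),
            class = "NetSpec")
}

#' Training configuration for the classifier
#'
#' Constant learning rate 1e-4 with the Adam optimizer and cross-entropy
#' loss on the softmax outputs; mini-batches are stratified so every batch
#' contains at least `minMinority` samples of the minority class (see
#' [stratifiedBatches()]).
#'
#' @param learningRate constant learning rate (`>= 0`; 0 freezes weights).
#' @param batchSize mini-batch size.
#' @param epochs number of passes over the majority class.
#' @param minMinority minimum minority-class samples per batch, `>= 1` and
#'   `<= batchSize / 2`.
#' @param seed RNG seed covering initialization, batching and dropout.
#' @param augment if `TRUE`, each training sample is a patch drawn at
#'   random from its 15-patch augmentation set ([augmentDisc()]) instead of
#'   the deterministic centre crop.
#' @param beta1,beta2,epsilon Adam moment decay rates and stabilizer.
#' @return A validated list of class `TrainConfig`.
#' @export
trainConfig <- function(learningRate = 1e-4, batchSize = 32, epochs = 10,
                        minMinority = 4, seed = 1, augment = FALSE,
                        beta1 = 0.9, beta2 = 0.999, epsilon = 1e-8) {
  stopifnot(learningRate >= 0, batchSize >= 2, epochs >= 1,
            minMinority >= 1, minMinority <= batchSize / 2)
  structure(list(learningRate = learningRate,
                 batchSize = as.integer(batchSize),
                 epochs = as.integer(epochs),
                 minMinority = as.integer(minMinority),
                 seed = as.integer(seed), augment = isTRUE(augment),
                 beta1 = beta1, beta2 = beta2, epsilon = epsilon),
            class = "TrainConfig")
}

# Spatial sizes of every stage for a given input size; errors out if a
# feature map collapses below the next kernel or pool window.
netShapes <- function(spec, inputSize) {
  sz <- inputSize; ch <- 3L
  shapes <- list()
  for (i in seq_along(spec$conv)) {
    l <- spec$conv[[i]]
    if (sz + 2 * l$pad < l$size) {
      stop("spatial size collapsed below kernel at conv", i)
    }
    sz <- (sz + 2 * l$pad - l$size) %/% l$stride + 1L
    if (l$pool) {
      if (sz < spec$pool$p) stop("spatial size collapsed at pool", i)
      sz <- (sz - spec$pool$p) %/% spec$pool$s + 1L
    }
    ch <- l$k
    shapes[[i]] <- c(size = sz, channels = ch)
  }
  list(conv = shapes, flat = sz * sz * ch)
}

#' Build (initialize) the classification network
#'
#' Validates the architecture against the input size and draws the initial
#' weights (He-scaled Gaussians, zero biases) under `seed`.
#'
#' @param spec a [netSpec()].
#' @param inputSize side of the square input patch (227 for the standard
#'   crop of a 256 disc image).
#' @param seed RNG seed for the weight draw.
#' @return A model object of class `odNet` holding the spec, shapes and
#'   parameters.
#' @export
buildNetwork <- function(spec = netSpec(), inputSize = 227, seed = 1) {
  shapes <- netShapes(spec, inputSize)
  withSeed(seed, {
    params <- list(conv = list(), fc = list())
    cin <- 3L
    for (i in seq_along(spec$conv)) {
      l <- spec$conv[[i]]
      fanIn <- l$size^2 * cin
      params$conv[[i]] <- list(
        w = matrix(stats::rnorm(fanIn * l$k, 0, sqrt(2 / fanIn)),
                   fanIn, l$k),
        b = numeric(l$k))
      cin <- l$k
    }
    widths <- c(shapes$flat, spec$fcWidths, spec$nClasses)
    for (i in seq_len(length(widths) - 1L)) {
      params$fc[[i]] <- list(
        w = matrix(stats::rnorm(widths[i] * widths[i + 1], 0,
                                sqrt(2 / widths[i])),
                   widths[i], widths[i + 1]),
        b = numeric(widths[i + 1]))
    }
    structure(list(spec = spec, inputSize = as.integer(inputSize),
                   shapes = shapes, params = params,
                   classes = c("healthy", "glaucoma")[seq_len(
                     min(2L, spec$nClasses))]),
              class = "odNet")
  })
}

#' @export
print.odNet <- function(x, ...) {
  k <- vapply(x$spec$conv, function(l) l$k, 0)
  cat(sprintf(
    "odNet: input %dx%dx3, conv %s, fc %s -> %d classes (softmax)\n",
    x$inputSize, x$inputSize, paste(k, collapse = "-"),
    paste(x$spec$fcWidths, collapse = "-"), x$spec$nClasses))
  invisible(x)
}

relu <- function(x) { x[x < 0] <- 0; x }

softmaxRows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Forward pass.  x: (H, W, 3, N) array already normalized to roughly
# [-0.5, 0.5].  Returns probabilities and, if keepCache, everything the
# backward pass needs.  Dropout masks must be supplied for training mode.
netForward <- function(model, x, dropMasks = NULL, keepCache = FALSE) {
  spec <- model$spec
  cache <- list(conv = list(), fc = list())
  cur <- x
  for (i in seq_along(spec$conv)) {
    l <- spec$conv[[i]]
    p <- model$params$conv[[i]]
    st <- list(xin = if (keepCache) cur else NULL)
    z <- cppConvForward(cur, p$w, p$b, l$size, l$size, l$stride, l$pad)
    a <- relu(z)
    if (keepCache) { st$mask <- z > 0 }
    if (l$lrn) {
      lf <- cppLrnForward(a, spec$lrn$n, spec$lrn$k, spec$lrn$alpha,
                          spec$lrn$beta)
      if (keepCache) {
        st$lrnIn <- a; st$lrnOut <- lf$out; st$lrnDenom <- lf$denom
      }
      a <- lf$out
    }
    if (l$pool) {
      if (keepCache) st$poolInDim <- dim(a)
      pf <- cppMaxPoolForward(a, spec$pool$p, spec$pool$s)
      if (keepCache) st$poolArgmax <- pf$argmax
      a <- pf$out
    }
    cache$conv[[i]] <- st
    cur <- a
  }
  flatDim <- dim(cur)
  X <- t(matrix(cur, prod(flatDim[1:3]), flatDim[4]))
  nFc <- length(model$params$fc)
  for (i in seq_len(nFc)) {
    p <- model$params$fc[[i]]
    z <- X %*% p$w
    z <- sweep(z, 2, p$b, "+")
    if (i < nFc) {
      a <- relu(z)
      if (!is.null(dropMasks) && spec$dropout > 0) {
        a <- a * dropMasks[[i]]
      }
      cache$fc[[i]] <- list(xin = if (keepCache) X else NULL,
                            mask = if (keepCache) z > 0 else NULL)
      X <- a
    } else {
      cache$fc[[i]] <- list(xin = if (keepCache) X else NULL)
      X <- z
    }
  }
  probs <- softmaxRows(X)
  list(probs = probs, cache = if (keepCache) cache else NULL,
       flatDim = flatDim)
}

# Backward pass from softmax cross-entropy.  y: integer class index (1-based)
# per sample.  Returns gradients in the same structure as model$params.
netBackward <- function(model, fwd, y, dropMasks = NULL) {
  spec <- model$spec
  probs <- fwd$probs
  n <- nrow(probs)
  dZ <- probs
  dZ[cbind(seq_len(n), y)] <- dZ[cbind(seq_len(n), y)] - 1
  dZ <- dZ / n
  grads <- list(conv = vector("list", length(model$params$conv)),
                fc = vector("list", length(model$params$fc)))
  for (i in rev(seq_along(model$params$fc))) {
    st <- fwd$cache$fc[[i]]
    p <- model$params$fc[[i]]
    grads$fc[[i]] <- list(w = crossprod(st$xin, dZ), b = colSums(dZ))
    dX <- tcrossprod(dZ, p$w)
    if (i > 1L) {
      if (!is.null(dropMasks) && spec$dropout > 0) {
        dX <- dX * dropMasks[[i - 1L]]
      }
      dX <- dX * fwd$cache$fc[[i - 1L]]$mask
    }
    dZ <- dX
  }
  dCur <- array(t(dZ), fwd$flatDim)
  for (i in rev(seq_along(spec$conv))) {
    l <- spec$conv[[i]]
    st <- fwd$cache$conv[[i]]
    p <- model$params$conv[[i]]
    if (l$pool) {
      dCur <- cppMaxPoolBackward(dCur, st$poolArgmax,
                                 as.integer(st$poolInDim))
    }
    if (l$lrn) {
      dCur <- cppLrnBackward(st$lrnIn, st$lrnOut, st$lrnDenom, dCur,
                             spec$lrn$n, spec$lrn$alpha, spec$lrn$beta)
    }
    dCur <- dCur * st$mask
    bw <- cppConvBackward(st$xin, p$w, dCur, l$size, l$size, l$stride,
                          l$pad, i > 1L)
    grads$conv[[i]] <- list(w = bw$dw, b = bw$db)
    if (i > 1L) dCur <- bw$dx
  }
  grads
}

# One Adam step over all parameters; state holds first/second moments and
# the step counter.
adamStep <- function(params, grads, state, config) {
  state$t <- state$t + 1L
  lr <- config$learningRate
  b1 <- config$beta1; b2 <- config$beta2; eps <- config$epsilon
  corr <- lr * sqrt(1 - b2^state$t) / (1 - b1^state$t)
  for (grp in c("conv", "fc")) {
    for (i in seq_along(params[[grp]])) {
      for (nm in c("w", "b")) {
        g <- grads[[grp]][[i]][[nm]]
        m <- b1 * state$m[[grp]][[i]][[nm]] + (1 - b1) * g
        v <- b2 * state$v[[grp]][[i]][[nm]] + (1 - b2) * g^2
        state$m[[grp]][[i]][[nm]] <- m
        state$v[[grp]][[i]][[nm]] <- v
        params[[grp]][[i]][[nm]] <-
          params[[grp]][[i]][[nm]] - corr * m / (sqrt(v) + eps)
      }
    }
  }
  list(params = params, state = state)
}

zeroLike <- function(params) {
  lapply(params, function(grp) lapply(grp, function(p) {
    list(w = array(0, dim(p$w) %||% length(p$w)), b = numeric(length(p$b)))
  }))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
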