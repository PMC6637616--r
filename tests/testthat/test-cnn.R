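test_that("disc extraction crops, clips and resizes to the fixed input size", {
  res <- smallScene()
  d <- extractDisc(res$image, res$gt@odBox)
  expect_identical(dim(imagePixels(d)), c(256L, 256L, 3L))
  # a box partly outside the frame is clipped, not an error
  edge <- boundingBox(-20, -20, 100, 100)
  expect_identical(dim(imagePixels(extractDisc(res$image, edge))),
                   c(256L, 256L, 3L))
  # a fully external box is rejected
  expect_error(extractDisc(res$image, boundingBox(1000, 1000, 1100, 1100)),
               "does not intersect")
  # whole-image box is just a resize
  full <- extractDisc(res$image, boundingBox(0, 0, 600, 600), outSize = 128)
  ref <- resizeFundus(res$image, 128, 128)
  expect_identical(imagePixels(full), imagePixels(ref))
})

test_that("the extracted disc contains the cup at its mapped position", {
  sp <- syntheticSpec(imageSize = 600, cdr = 0.8, seed = 6)
  res <- generateImage(sp)
  d <- extractDisc(res$image, res$gt@odBox)
  # the cup (pale, bright) centre maps to the crop centre; compare mean
  # luminance of the central patch to the crop border
  lum <- luminance(d)
  centre <- lum[118:138, 118:138]
  border <- lum[1:10, ]
  expect_gt(mean(centre), mean(border) + 30)
})

test_that("augmentation yields exactly 15 patches with exact flip algebra", {
  res <- smallScene()
  d <- extractDisc(res$image, res$gt@odBox)
  patches <- augmentDisc(d)
  expect_identical(length(patches), 15L)
  expect_true(all(vapply(patches, function(p) {
    identical(dim(p), c(227L, 227L, 3L))
  }, TRUE)))
  expect_identical(length(unique(names(patches))), 15L)
  # flipping an h-flipped patch recovers the identity patch pixelwise
  flipH <- function(px) px[, rev(seq_len(ncol(px))), , drop = FALSE]
  expect_identical(flipH(patches$center_hflip), patches$center_identity)
  expect_identical(flipH(patches$tl_hflip), patches$tl_identity)
  expect_error(augmentDisc(extractDisc(res$image, res$gt@odBox,
                                       outSize = 128)), "larger")
})

test_that("stratified batches keep the minority floor and cover the majority", {
  labels <- rep(c("healthy", "glaucoma"), c(482, 168))
  for (seed in 1:3) {
    batches <- stratifiedBatches(labels, batchSize = 32, minMinority = 4,
                                 seed = seed)
    glaucomaPerBatch <- vapply(batches, function(b) {
      sum(labels[b] == "glaucoma")
    }, 0L)
    expect_true(all(glaucomaPerBatch >= 4))
    expect_true(all(lengths(batches) == 32))
    majUsed <- unlist(lapply(batches, function(b) b[labels[b] == "healthy"]),
                      use.names = FALSE)
    expect_identical(sort(majUsed), which(labels == "healthy"))
  }
  # balanced tiny set: constraint satisfiable without repeats
  b <- stratifiedBatches(rep(c("healthy", "glaucoma"), each = 4),
                         batchSize = 4, minMinority = 1, seed = 1)
  expect_true(all(vapply(b, anyDuplicated, 0L) == 0L))
  expect_error(stratifiedBatches(rep("healthy", 10), 4, 1), "both classes")
})

test_that("the network forward pass is a valid softmax classifier", {
  model <- buildNetwork(tinyNetSpec(), inputSize = 67, seed = 2)
  ns <- asNamespace("fundusOD")
  x <- array(rnorm(67 * 67 * 3 * 4, 0, 0.3), c(67, 67, 3, 4))
  f <- ns$netForward(model, x)
  expect_identical(dim(f$probs), c(4L, 2L))
  expect_equal(rowSums(f$probs), rep(1, 4), tolerance = 1e-6)
  # all-zero input stays finite
  f0 <- ns$netForward(model, array(0, c(67, 67, 3, 2)))
  expect_true(all(is.finite(f0$probs)))
  # deterministic: same weights, same input, same output
  f2 <- ns$netForward(model, x)
  expect_identical(f$probs, f2$probs)
  # an input too small for the architecture is rejected at build time
  expect_error(buildNetwork(tinyNetSpec(), inputSize = 40), "collapsed")
})

test_that("analytic gradients match finite differences", {
  ns <- asNamespace("fundusOD")
  spec <- netSpec(convKernels = c(2, 2, 2, 2), fcWidths = c(4, 3))
  model <- buildNetwork(spec, inputSize = 67, seed = 3)
  set.seed(4)
  x <- array(rnorm(67 * 67 * 3 * 2, 0, 0.3), c(67, 67, 3, 2))
  y <- c(1L, 2L)
  lossAt <- function(m) {
    f <- ns$netForward(m, x)
    -mean(log(f$probs[cbind(1:2, y)]))
  }
  fwd <- ns$netForward(model, x, keepCache = TRUE)
  gr <- ns$netBackward(model, fwd, y)
  eps <- 1e-5
  for (probe in list(c("conv", 1L), c("conv", 4L), c("fc", 1L), c("fc", 3L))) {
    grp <- probe[1]; i <- as.integer(probe[2])
    p <- model$params[[grp]][[i]]$w
    j <- sample(length(p), 1)
    up <- model; up$params[[grp]][[i]]$w[j] <- p[j] + eps
    dn <- model; dn$params[[grp]][[i]]$w[j] <- p[j] - eps
    num <- (lossAt(up) - lossAt(dn)) / (2 * eps)
    expect_equal(gr[[grp]][[i]]$w[j], num, tolerance = 1e-4)
  }
})

test_that("zero learning rate leaves the weights untouched", {
  ds <- tinyDiscSet()
  spec <- tinyNetSpec()
  cfg <- trainConfig(learningRate = 0, epochs = 1, batchSize = 8,
                     minMinority = 4, seed = 5)
  model0 <- buildNetwork(spec, inputSize = 67, seed = 5)
  fit <- trainNetwork(ds$discs, ds$labels, spec, cfg, inputSize = 67)
  expect_equal(fit$model$params, model0$params, tolerance = 1e-12)
  expect_identical(nrow(fit$history), 1L)
})

test_that("training reduces the loss on a separable toy problem", {
  ds <- tinyDiscSet()
  for (seed in c(1, 2, 3)) {
    cfg <- trainConfig(epochs = 6, batchSize = 8, minMinority = 4,
                       seed = seed)
    fit <- trainNetwork(ds$discs, ds$labels, tinyNetSpec(), cfg,
                        inputSize = 67)
    expect_identical(nrow(fit$history), 6L)
    expect_lt(fit$history$loss[6], fit$history$loss[1])
    # initial loss of a fresh 2-class softmax sits near ln(2)
    expect_lt(abs(fit$history$loss[1] - log(2)), 0.25)
  }
})

test_that("prediction is batch-order invariant and probabilistic", {
  ds <- tinyDiscSet()
  cfg <- trainConfig(epochs = 20, batchSize = 4, minMinority = 2, seed = 2)
  fit <- trainNetwork(ds$discs, ds$labels, tinyNetSpec(), cfg,
                      inputSize = 67)
  p <- predictNet(fit$model, ds$discs)
  expect_true(all(p >= 0 & p <= 1))
  perm <- sample(length(ds$discs))
  p2 <- predictNet(fit$model, ds$discs[perm])
  expect_equal(p2, p[perm], tolerance = 1e-12)
  # the learned score ranks high-CDR discs above low-CDR discs
  expect_gt(mean(p[ds$labels == "glaucoma"]), mean(p[ds$labels == "healthy"]))
})

test_that("predicted glaucoma probability increases along a CDR grid", {
  ds <- tinyDiscSet()
  cfg <- trainConfig(epochs = 40, batchSize = 4, minMinority = 2, seed = 3)
  fit <- trainNetwork(ds$discs, ds$labels, tinyNetSpec(), cfg,
                      inputSize = 67)
  grid <- c(0.3, 0.5, 0.7, 0.9)
  score <- vapply(seq_along(grid), function(i) {
    sp <- syntheticSpec(imageSize = 300, cdr = grid[i], seed = 200 + i)
    res <- generateImage(sp)
    mean(predictNet(fit$model,
                    list(extractDisc(res$image, res$gt@odBox,
                                     outSize = 72))))
  }, 0)
  expect_gt(cor(score, grid, method = "spearman"), 0)
})

test_that("cross-validation aggregates per-fold reports", {
  ds <- tinyDiscSet()
  cfg <- trainConfig(epochs = 4, batchSize = 8, minMinority = 4, seed = 6)
  cv <- crossValidate(ds$discs, ds$labels, k = 3, spec = tinyNetSpec(),
                      config = cfg, inputSize = 67, seed = 7)
  expect_identical(length(cv$folds), 3L)
  expect_identical(nrow(cv$summary), 4L)
  accs <- vapply(cv$folds, function(f) f$accuracy, 0)
  expect_equal(cv$summary$mean[cv$summary$metric == "accuracy"], mean(accs))
  expect_equal(cv$summary$sd[cv$summary$metric == "accuracy"],
               stats::sd(accs))
})

test_that("models round-trip through serialization with a JSON sidecar", {
  model <- buildNetwork(tinyNetSpec(), inputSize = 67, seed = 1)
  path <- tempfile(fileext = ".rds")
  saveModel(model, path)
  expect_true(file.exists(paste0(path, ".json")))
  back <- loadModel(path)
  expect_equal(back$params, model$params)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  expect_identical(side$inputSize, 67L)
})
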