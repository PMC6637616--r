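#' DiscImage: an extracted optic-disc crop
#'
#' A fixed-size RGB crop of the optic-disc region — the classifier's input
#' unit, since most glaucoma-related structure is contained in and around
#' the disc.  Inherits the raster slots of [FundusImage-class]; the `label`
#' slot is `NA` for unlabelled discs.
#'
#' @slot label `"healthy"`, `"glaucoma"` or `NA`.
#' @export
setClass("DiscImage", contains = "FundusImage",
         representation(label = "character"),
  validity = function(object) {
    d <- dim(object@pixels)
    if (d[1] != d[2]) return("disc crops must be square")
    if (!is.na(object@label) &&
        !object@label %in% c("healthy", "glaucoma")) {
      return("label must be healthy, glaucoma or NA")
    }
    TRUE
  })

setMethod("show", "DiscImage", function(object) {
  cat(sprintf("DiscImage '%s': %d x %d x 3, label %s\n", object@imageId,
              nrow(object@pixels), ncol(object@pixels), object@label))
})

#' Extract the optic-disc region from a fundus image
#'
#' Clips the box to the image bounds, crops, and resizes the crop to
#' `outSize` x `outSize` with bilinear interpolation.
#'
#' @param image a [FundusImage-class].
#' @param box a [BoundingBox-class] locating the disc.
#' @param outSize output side length (256 for the standard pipeline).
#' @param label optional class label carried along.
#' @return A [DiscImage-class].
#' @export
extractDisc <- function(image, box, outSize = 256, label = NA_character_) {
  d <- dim(image@pixels)
  x0 <- max(0L, box@xMin); x1 <- min(d[2], box@xMax)
  y0 <- max(0L, box@yMin); y1 <- min(d[1], box@yMax)
  if (x0 >= x1 || y0 >= y1) {
    stop("box does not intersect the image")
  }
  crop <- image@pixels[(y0 + 1):y1, (x0 + 1):x1, , drop = FALSE]
  eb <- EBImage::Image(toEB(crop / 255), colormode = "Color")
  out <- EBImage::resize(eb, w = outSize, h = outSize, filter = "bilinear")
  px <- clamp(roundHalfUp(fromEB(out) * 255), 0, 255)
  storage.mode(px) <- "integer"
  new("DiscImage", pixels = px, imageId = image@imageId,
      originalSize = c(as.integer(outSize), as.integer(outSize)),
      label = as.character(label))
}

cropPatch <- function(px, oy, ox, size) {
  px[(oy + 1):(oy + size), (ox + 1):(ox + size), , drop = FALSE]
}

flipH <- function(px) px[, rev(seq_len(ncol(px))), , drop = FALSE]
flipV <- function(px) px[rev(seq_len(nrow(px))), , , drop = FALSE]

# The five crop offsets (0-based) of a `from`-sized image for `size` patches.
cropOffsets <- function(from, size) {
  m <- from - size
  c2 <- m %/% 2L
  list(tl = c(0L, 0L), tr = c(0L, m), bl = c(m, 0L), br = c(m, m),
       center = c(c2, c2))
}

#' Deterministic 15-patch augmentation of a disc crop
#'
#' The full product of \{identity, horizontal flip, vertical flip\} with
#' the five standard crops (four corners and centre) of a 256-pixel disc
#' image: exactly 15 patches of `patchSize` x `patchSize` x 3.  Flips are
#' applied to the cropped patch, so flipping a flipped patch recovers the
#' identity patch exactly.
#'
#' @param disc a [DiscImage-class] of size 256 (more generally, larger than
#'   `patchSize`).
#' @param patchSize patch side length, default 227.
#' @return Named list of 15 integer arrays `patchSize x patchSize x 3`,
#'   names like `"center_identity"`, `"tl_hflip"`.
#' @export
augmentDisc <- function(disc, patchSize = 227) {
  px <- imagePixels(disc)
  if (nrow(px) <= patchSize) {
    stop("disc image must be larger than the patch size (expected 256)")
  }
  offs <- cropOffsets(nrow(px), patchSize)
  out <- list()
  for (cn in names(offs)) {
    patch <- cropPatch(px, offs[[cn]][1], offs[[cn]][2], patchSize)
    out[[paste0(cn, "_identity")]] <- patch
    out[[paste0(cn, "_hflip")]] <- flipH(patch)
    out[[paste0(cn, "_vflip")]] <- flipV(patch)
  }
  out
}

# Stack a list of discs into a normalized (size, size, 3, N) batch tensor,
# taking the centre crop (or a caller-chosen patch per disc).
discBatch <- function(discs, idx, size, patchPick = NULL) {
  n <- length(idx)
  x <- array(0, c(size, size, 3L, n))
  for (j in seq_len(n)) {
    px <- imagePixels(discs[[idx[j]]])
    if (is.null(patchPick)) {
      off <- cropOffsets(nrow(px), size)$center
      patch <- cropPatch(px, off[1], off[2], size)
    } else {
      patch <- patchPick(px, j)
    }
    x[, , , j] <- patch
  }
  x / 255 - 0.5
}

#' Stratified mini-batches for imbalanced training
#'
#' Splits an epoch so that every majority-class sample appears exactly
#' once, while every batch is topped up with at least `minMinority`
#' minority-class samples (repeating minority samples — oversampling — as
#' needed).  This prevents batches without any glaucoma image, the failure
#' mode of plain shuffling on imbalanced screening data.
#'
#' @param labels class-name vector for the dataset (both classes present).
#' @param batchSize target batch size.
#' @param minMinority minimum minority samples per batch.
#' @param seed RNG seed; batches are deterministic under it.
#' @return List of integer index vectors (1-based into `labels`).
#' @export
stratifiedBatches <- function(labels, batchSize = 32, minMinority = 4,
                              seed = 1) {
  labels <- as.character(labels)
  tab <- table(labels)
  if (length(tab) < 2L) stop("dataset must contain both classes")
  stopifnot(minMinority >= 1, minMinority <= batchSize / 2)
  minority <- names(tab)[which.min(tab)]
  minIdx <- which(labels == minority)
  majIdx <- which(labels != minority)
  withSeed(seed, {
    maj <- sample(majIdx)
    nBatches <- ceiling(length(maj) / (batchSize - minMinority))
    chunks <- split(maj, rep(seq_len(nBatches),
                             each = ceiling(length(maj) / nBatches),
                             length.out = length(maj)))
    pool <- integer(0)
    lapply(chunks, function(ch) {
      need <- max(minMinority, batchSize - length(ch))
      take <- integer(0)
      while (length(take) < need) {
        if (!length(pool)) pool <<- sample(minIdx)
        k <- min(need - length(take), length(pool))
        take <- c(take, pool[seq_len(k)])
        pool <<- pool[-seq_len(k)]
      }
      sample(c(ch, take))
    })
  })
}

#' Train the classifier
#'
#' Runs `config$epochs` epochs of stratified mini-batches, minimizing
#' softmax cross-entropy with Adam at a constant learning rate.  All
#' randomness (weight init, batching, dropout, augmentation picks) is
#' governed by `config$seed`, so a rerun reproduces the same model.
#'
#' @param discs list of labelled [DiscImage-class] objects.
#' @param labels class-name vector parallel to `discs` (defaults to the
#'   discs' own labels).
#' @param spec a [netSpec()].
#' @param config a [trainConfig()].
#' @param inputSize network input patch side (227 for 256 discs).
#' @param model optionally continue training an existing `odNet`.
#' @return `list(model, history)`; `history` is a data frame with one row
#'   per epoch (`epoch, loss, accuracy`), mean training loss and accuracy.
#' @export
trainNetwork <- function(discs, labels = NULL, spec = netSpec(),
                         config = trainConfig(), inputSize = 227,
                         model = NULL) {
  if (is.null(labels)) {
    labels <- vapply(discs, function(d) d@label, "")
  }
  labels <- as.character(labels)
  if (length(unique(labels)) < 2L) {
    stop("training data must contain both classes")
  }
  if (is.null(model)) {
    model <- buildNetwork(spec, inputSize, seed = config$seed)
  }
  classes <- model$classes
  y <- match(labels, classes)
  if (anyNA(y)) stop("labels must be in {", paste(classes, collapse = ", "), "}")
  state <- list(m = zeroLike(model$params), v = zeroLike(model$params),
                t = 0L)
  seeds <- deriveSeeds(config$seed + 1L, config$epochs)
  history <- data.frame(epoch = seq_len(config$epochs), loss = NA_real_,
                        accuracy = NA_real_)
  for (ep in seq_len(config$epochs)) {
    batches <- stratifiedBatches(labels, config$batchSize,
                                 config$minMinority, seed = seeds[ep])
    epLoss <- 0; epCorrect <- 0; epN <- 0
    withSeed(seeds[ep] + 1L, {
      for (b in batches) {
        pick <- NULL
        if (config$augment) {
          pick <- function(px, j) {
            offs <- cropOffsets(nrow(px), model$inputSize)
            off <- offs[[sample.int(5L, 1L)]]
            patch <- cropPatch(px, off[1], off[2], model$inputSize)
            switch(sample.int(3L, 1L), patch, flipH(patch), flipV(patch))
          }
        }
        x <- discBatch(discs, b, model$inputSize, pick)
        masks <- NULL
        if (model$spec$dropout > 0) {
          masks <- lapply(model$spec$fcWidths, function(wd) {
            (matrix(stats::runif(length(b) * wd), length(b), wd) >=
               model$spec$dropout) / (1 - model$spec$dropout)
          })
        }
        fwd <- netForward(model, x, dropMasks = masks, keepCache = TRUE)
        yb <- y[b]
        pb <- pmax(fwd$probs[cbind(seq_along(b), yb)], 1e-12)
        epLoss <- epLoss - sum(log(pb))
        epCorrect <- epCorrect +
          sum(max.col(fwd$probs, ties.method = "first") == yb)
        epN <- epN + length(b)
        grads <- netBackward(model, fwd, yb, dropMasks = masks)
        up <- adamStep(model$params, grads, state, config)
        model$params <- up$params
        state <- up$state
      }
    })
    history$loss[ep] <- epLoss / epN
    history$accuracy[ep] <- epCorrect / epN
    logMsg("INFO", sprintf("epoch %d/%d: loss %.4f, accuracy %.3f", ep,
                           config$epochs, history$loss[ep],
                           history$accuracy[ep]))
  }
  list(model = model, history = history)
}

#' Predict glaucoma probabilities for disc crops
#'
#' Test-time inference uses the deterministic centre crop only (no
#' augmentation) and no dropout; outputs are softmax probabilities.
#'
#' @param model a trained `odNet`.
#' @param discs list of [DiscImage-class] objects.
#' @param batchSize inference batch size.
#' @return Numeric vector of `p(glaucoma)` in `[0, 1]`, one per disc.
#' @export
predictNet <- function(model, discs, batchSize = 32) {
  n <- length(discs)
  out <- numeric(n)
  posCol <- match("glaucoma", model$classes)
  i <- 1L
  while (i <= n) {
    idx <- i:min(n, i + batchSize - 1L)
    x <- discBatch(discs, idx, model$inputSize)
    fwd <- netForward(model, x, dropMasks = NULL, keepCache = FALSE)
    out[idx] <- fwd$probs[, posCol]
    i <- i + batchSize
  }
  out
}

#' Cross-validated evaluation of the classifier
#'
#' Splits the discs into `k` class-stratified folds, trains on `k - 1` and
#' tests on the held-out fold, and aggregates accuracy, support-weighted
#' precision and F1, and AUC over the folds (mean and sample standard
#' deviation).
#'
#' @param discs list of labelled [DiscImage-class] objects.
#' @param labels class-name vector (defaults to the discs' labels).
#' @param k number of folds.
#' @param spec,config network architecture and training settings.
#' @param inputSize network input patch side.
#' @param seed seed for the fold split; per-fold training seeds derive from
#'   `config$seed`.
#' @return A list of class `CrossValidation`: `folds` (per-fold
#'   `ClassificationReport` plus `auc` and `accuracy`), and `summary`, a
#'   data frame of mean and sd per metric.
#' @export
crossValidate <- function(discs, labels = NULL, k = 10, spec = netSpec(),
                          config = trainConfig(), inputSize = 227,
                          seed = 1) {
  if (is.null(labels)) labels <- vapply(discs, function(d) d@label, "")
  labels <- as.character(labels)
  if (length(discs) < k) stop("need at least k samples")
  ids <- as.character(seq_along(discs))
  split <- kfoldSplit(ids, k, seed = seed, stratify = labels)
  foldSeeds <- deriveSeeds(config$seed, k)
  folds <- vector("list", k)
  metrics <- matrix(NA_real_, k, 4,
                    dimnames = list(NULL, c("accuracy", "precision", "f1",
                                            "auc")))
  for (f in seq_len(k)) {
    test <- which(split$assignment == f - 1L)
    train <- setdiff(seq_along(discs), test)
    if (length(unique(labels[train])) < 2L) {
      stop("training partition of fold ", f, " is single-class")
    }
    cfg <- config
    cfg$seed <- foldSeeds[f]
    fit <- trainNetwork(discs[train], labels[train], spec, cfg, inputSize)
    scores <- predictNet(fit$model, discs[test])
    preds <- ifelse(scores > 0.5, "glaucoma", "healthy")
    rep <- classificationReport(labels[test], preds,
                                classes = c("healthy", "glaucoma"),
                                strict = FALSE)
    auc <- if (length(unique(labels[test])) == 2L) {
      rocAuc(scores, labels[test])$auc
    } else NA_real_
    metrics[f, ] <- c(rep$total$accuracy, rep$total$precision,
                      rep$total$f1, auc)
    folds[[f]] <- list(report = rep, auc = auc,
                       accuracy = rep$total$accuracy,
                       history = fit$history)
  }
  summary <- data.frame(metric = colnames(metrics),
                        mean = colMeans(metrics, na.rm = TRUE),
                        sd = apply(metrics, 2, stats::sd, na.rm = TRUE),
                        row.names = NULL)
  structure(list(folds = folds, summary = summary, k = k),
            class = "CrossValidation")
}

#' @export
print.CrossValidation <- function(x, ...) {
  cat(sprintf("CrossValidation over %d folds\n", x$k))
  print(x$summary, digits = 4)
  invisible(x)
}

#' Save / load a trained model
#'
#' The model is serialized with R's native format; a JSON sidecar with the
#' architecture and a weight checksum is written next to it so runs can be
#' audited without loading the binary.
#'
#' @param model an `odNet`.
#' @param path output `.rds` path.
#' @return `saveModel`: the path, invisibly; `loadModel`: the model.
#' @export
saveModel <- function(model, path) {
  saveRDS(model, path)
  k <- vapply(model$spec$conv, function(l) l$k, 0)
  sidecar <- list(inputSize = model$inputSize, convKernels = k,
                  fcWidths = model$spec$fcWidths,
                  dropout = model$spec$dropout,
                  nClasses = model$spec$nClasses,
                  nParams = sum(vapply(unlist(model$params,
                                              recursive = FALSE),
                                       function(p) length(p$w) + length(p$b),
                                       0)))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) readRDS(path)
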