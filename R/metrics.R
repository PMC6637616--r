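#' Confusion counts from label and prediction lists
#'
#' Tallies the truth-by-prediction contingency table.  Per-class
#' true/false positives/negatives follow the one-vs-rest convention, so in
#' the binary case the complementarity identities hold (the true positives
#' of one class are the true negatives of the other).
#'
#' @param labels,preds equal-length vectors of class names.
#' @param classes class name order; defaults to `c("healthy", "glaucoma")`
#'   when the data uses those names, otherwise the sorted union.
#' @return A [ConfusionCounts-class].
#' @examples
#' cc <- confusionCounts(c("healthy", "glaucoma"), c("healthy", "healthy"))
#' truePositives(cc, "healthy")
#' @export
confusionCounts <- function(labels, preds, classes = NULL) {
  if (length(labels) != length(preds)) {
    stop("labels and preds must have equal length")
  }
  if (length(labels) == 0L) stop("empty label list")
  labels <- as.character(labels); preds <- as.character(preds)
  if (is.null(classes)) {
    seen <- unique(c(labels, preds))
    classes <- if (all(seen %in% c("healthy", "glaucoma"))) {
      c("healthy", "glaucoma")
    } else sort(seen)
  }
  bad <- setdiff(unique(c(labels, preds)), classes)
  if (length(bad)) stop("unknown class(es): ", paste(bad, collapse = ", "))
  tab <- table(factor(labels, classes), factor(preds, classes))
  new("ConfusionCounts",
      table = matrix(as.integer(tab), length(classes),
                     dimnames = dimnames(tab)),
      classes = classes)
}

setMethod("show", "ConfusionCounts", function(object) {
  cat("ConfusionCounts (rows = truth, cols = prediction)\n")
  print(object@table)
})

classIndex <- function(counts, class) {
  i <- match(class, counts@classes)
  if (is.na(i)) stop("unknown class '", class, "'")
  i
}

#' Per-class confusion tallies
#'
#' One-vs-rest views of a [ConfusionCounts-class]: `truePositives` etc.
#' return the TP/FP/FN/TN count of `class`.
#'
#' @param counts a [ConfusionCounts-class].
#' @param class class name.
#' @return Integer count.
#' @export
truePositives <- function(counts, class) {
  i <- classIndex(counts, class)
  counts@table[i, i]
}

#' @rdname truePositives
#' @export
falsePositives <- function(counts, class) {
  i <- classIndex(counts, class)
  sum(counts@table[, i]) - counts@table[i, i]
}

#' @rdname truePositives
#' @export
falseNegatives <- function(counts, class) {
  i <- classIndex(counts, class)
  sum(counts@table[i, ]) - counts@table[i, i]
}

#' @rdname truePositives
#' @export
trueNegatives <- function(counts, class) {
  sum(counts@table) - truePositives(counts, class) -
    falsePositives(counts, class) - falseNegatives(counts, class)
}

#' Precision, recall, F1 and specificity
#'
#' The standard screening metrics:
#' precision `= 100 TP / (TP + FP)`,
#' recall (sensitivity) `= 100 TP / (TP + FN)`,
#' specificity `= 100 TN / (TN + FP)`, and the F1 score as the harmonic
#' mean of precision and recall on the `[0, 1]` scale.  Undefined metrics
#' (zero denominators) raise an error rather than silently returning 0,
#' with the single documented exception `f1Score(0, 0) = 0`.
#'
#' @param counts a [ConfusionCounts-class].
#' @param class class name the metric is computed for.
#' @return Percent in `[0, 100]` (`f1Score`: ratio in `[0, 1]`).
#' @examples
#' cc <- confusionCounts(rep(c("healthy", "glaucoma"), c(3, 1)),
#'                       c("healthy", "healthy", "glaucoma", "glaucoma"))
#' classPrecision(cc, "healthy")
#' @export
classPrecision <- function(counts, class) {
  tp <- truePositives(counts, class); fp <- falsePositives(counts, class)
  if (tp + fp == 0) {
    stop("precision undefined for class '", class, "' (no predictions)")
  }
  100 * tp / (tp + fp)
}

#' @rdname classPrecision
#' @export
classRecall <- function(counts, class) {
  tp <- truePositives(counts, class); fn <- falseNegatives(counts, class)
  if (tp + fn == 0) {
    stop("recall undefined for class '", class, "' (no support)")
  }
  100 * tp / (tp + fn)
}

#' @rdname classPrecision
#' @export
classSpecificity <- function(counts, class) {
  tn <- trueNegatives(counts, class); fp <- falsePositives(counts, class)
  if (tn + fp == 0) {
    stop("specificity undefined for class '", class, "'")
  }
  100 * tn / (tn + fp)
}

#' @rdname classPrecision
#' @param precision,recall percent values as returned by the metric
#'   functions above.
#' @export
f1Score <- function(precision, recall) {
  p <- precision / 100; r <- recall / 100
  if (p + r == 0) return(0)
  2 * p * r / (p + r)
}

#' Full per-class classification report with weighted totals
#'
#' Per-class precision, recall, F1 and support, plus support-weighted total
#' precision and F1 and the overall accuracy — the layout screening studies
#' tabulate so that performance on the minority (glaucoma) class is visible
#' next to the headline accuracy.
#'
#' @param labels,preds equal-length class-name vectors.
#' @param classes optional class order (see [confusionCounts()]).
#' @param strict if `TRUE` (default) an undefined per-class metric raises an
#'   error, matching the single-metric functions; with `strict = FALSE` a
#'   class that was never predicted gets `NA` precision (and `NA` F1), as
#'   needed when aggregating many small cross-validation folds.
#' @return A list of class `ClassificationReport`: `per_class` data frame
#'   (`class, precision, recall, f1, support`), `total` (list with
#'   support-weighted `precision` and `f1`, overall `accuracy`, total
#'   `support`), and `counts` (the [ConfusionCounts-class]).
#' @export
classificationReport <- function(labels, preds, classes = NULL,
                                 strict = TRUE) {
  counts <- confusionCounts(labels, preds, classes)
  cls <- counts@classes
  metricOf <- function(fn) vapply(cls, function(c) {
    if (strict) return(fn(counts, c))
    tryCatch(fn(counts, c), error = function(e) NA_real_)
  }, 0)
  per <- data.frame(
    class = cls,
    precision = metricOf(classPrecision),
    recall = metricOf(classRecall),
    f1 = NA_real_, support = vapply(cls, function(c) {
      truePositives(counts, c) + falseNegatives(counts, c)
    }, 0), row.names = NULL, stringsAsFactors = FALSE)
  per$f1 <- vapply(seq_along(cls), function(i) {
    if (is.na(per$precision[i]) || is.na(per$recall[i])) return(NA_real_)
    f1Score(per$precision[i], per$recall[i])
  }, 0)
  total <- list(
    precision = sum(per$precision * per$support) / sum(per$support),
    accuracy = 100 * sum(diag(counts@table)) / sum(counts@table),
    f1 = sum(per$f1 * per$support) / sum(per$support),
    support = sum(per$support))
  structure(list(per_class = per, total = total, counts = counts),
            class = "ClassificationReport")
}

#' @export
print.ClassificationReport <- function(x, ...) {
  cat("ClassificationReport\n")
  print(x$per_class, digits = 4)
  cat(sprintf(
    "Total: precision %.2f%%, accuracy %.2f%%, F1 %.4f (n = %d)\n",
    x$total$precision, x$total$accuracy, x$total$f1, x$total$support))
  invisible(x)
}

#' ROC curve and AUC for a binary score
#'
#' Sweeps a threshold over the scores (confidence of the positive class)
#' and records sensitivity and specificity at every distinct threshold.
#' The AUC is obtained by trapezoidal integration of sensitivity against
#' the false-positive rate, which equals the concordance probability
#' `P(score_pos > score_neg) + 0.5 P(tie)`.
#'
#' @param scores numeric scores, larger = more likely positive.
#' @param labels class names; both classes must be present.
#' @param positive name of the positive class.
#' @return A list of class `ROCCurve`: `points` data frame
#'   (`threshold, sensitivity, specificity`, percent), `auc` in `[0, 1]`,
#'   and `positive`.
#' @examples
#' rocAuc(c(0.9, 0.8, 0.7), c("glaucoma", "glaucoma", "healthy"))$auc
#' @export
rocAuc <- function(scores, labels, positive = "glaucoma") {
  stopifnot(length(scores) == length(labels))
  isPos <- as.character(labels) == positive
  nP <- sum(isPos); nN <- sum(!isPos)
  if (nP == 0L || nN == 0L) {
    stop("both classes must be present to build a ROC curve")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- isPos[ord]
  # cumulative counts at each distinct threshold (predict positive if
  # score >= threshold); take the last index of each tie group
  grp <- !duplicated(s, fromLast = TRUE)
  tp <- cumsum(p)[grp]; fp <- cumsum(!p)[grp]
  thr <- s[grp]
  sens <- c(0, tp / nP); fpr <- c(0, fp / nN)
  auc <- sum(diff(fpr) * (utils::head(sens, -1) + utils::tail(sens, -1)) / 2)
  points <- data.frame(threshold = c(Inf, thr),
                       sensitivity = 100 * sens,
                       specificity = 100 * (1 - fpr))
  structure(list(points = points, auc = auc, positive = positive),
            class = "ROCCurve")
}

#' @export
print.ROCCurve <- function(x, ...) {
  cat(sprintf("ROCCurve (%d points, positive = '%s'): AUC = %.4f\n",
              nrow(x$points), x$positive, x$auc))
  invisible(x)
}

#' Sensitivity at a fixed observed specificity
#'
#' Reads the ROC step function without interpolation: the highest
#' sensitivity among operating points whose specificity is at least
#' `target`.  This is the conservative reading used when comparing
#' screening classifiers at a quoted specificity (e.g. 85\%).
#'
#' @param curve a `ROCCurve` from [rocAuc()].
#' @param target specificity in percent, in `(0, 100]`.
#' @return Sensitivity in percent.
#' @export
sensitivityAtSpecificity <- function(curve, target) {
  if (!is.numeric(target) || target <= 0 || target > 100) {
    stop("target specificity must lie in (0, 100]")
  }
  ok <- curve$points$specificity >= target
  if (!any(ok)) return(0)
  max(curve$points$sensitivity[ok])
}

#' Random k-fold split of image ids
#'
#' Deterministic under `seed`; fold sizes differ by at most one.  With
#' `stratify`, ids are split within each stratum first so every fold keeps
#' the class proportions (recommended for imbalanced data, where plain
#' random folds at small n can lose a class entirely).
#'
#' @param ids character vector of unique ids.
#' @param k number of folds, `2 <= k <= length(ids)`.
#' @param seed RNG seed.
#' @param stratify optional vector, parallel to `ids`, of stratum labels.
#' @return A list of class `FoldSplit`: `k` and `assignment`, a named
#'   integer vector mapping each id to a fold index in `0:(k-1)`.
#' @examples
#' table(kfoldSplit(as.character(1:650), 10, seed = 1)$assignment)
#' @export
kfoldSplit <- function(ids, k, seed = 1, stratify = NULL) {
  n <- length(ids)
  if (anyDuplicated(ids)) stop("ids must be unique")
  if (k < 2 || k > n) stop("k must lie in [2, length(ids)]")
  assignment <- withSeed(seed, {
    out <- integer(n)
    if (is.null(stratify)) {
      out[sample.int(n)] <- rep_len(0:(k - 1), n)
    } else {
      stopifnot(length(stratify) == n)
      offset <- 0L  # rotate fold order between strata to balance sizes
      for (s in unique(stratify)) {
        j <- which(stratify == s)
        folds <- (rep_len(0:(k - 1), length(j)) + offset) %% k
        out[j[sample.int(length(j))]] <- folds
        offset <- (offset + length(j)) %% k
      }
    }
    out
  })
  names(assignment) <- ids
  structure(list(k = as.integer(k), assignment = assignment),
            class = "FoldSplit")
}
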