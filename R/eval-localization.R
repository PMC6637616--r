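#' Intersection over union of two boxes
#'
#' `area(a ∩ b) / area(a ∪ b)` under the half-open convention; symmetric,
#' in `[0, 1]`, `0` for disjoint boxes.
#'
#' @param a,b [BoundingBox-class] objects.
#' @return Numeric scalar in `[0, 1]`.
#' @examples
#' iou(boundingBox(0, 0, 10, 10), boundingBox(5, 0, 15, 10))  # 1/3
#' @export
iou <- function(a, b) {
  inter <- intersectionArea(a, b)
  inter / (boxArea(a) + boxArea(b) - inter)
}

intersectionArea <- function(a, b) {
  w <- min(a@xMax, b@xMax) - max(a@xMin, b@xMin)
  h <- min(a@yMax, b@yMax) - max(a@yMin, b@yMin)
  if (w <= 0 || h <= 0) return(0)
  as.numeric(w) * as.numeric(h)
}

#' Fraction of the ground-truth box covered by the prediction
#'
#' `area(pred ∩ gt) / area(gt)`.  Asymmetric: it answers "how much of the
#' actual disc is present in the prediction", which is the quantity quoted
#' when a localizer's predictions are loose outer circles.
#'
#' @param pred,gt [BoundingBox-class] objects.
#' @return Numeric scalar in `[0, 1]`.
#' @export
coverageFraction <- function(pred, gt) {
  intersectionArea(pred, gt) / boxArea(gt)
}

#' The weak centre-distance localization criterion
#'
#' `TRUE` iff the Euclidean distance between the two box centres is
#' strictly less than the expected disc diameter, taken as the larger side
#' of the ground-truth box.  This is the permissive criterion — equivalent
#' to requiring only IOU > 0 for equal-size boxes — that some localization
#' literature scores against; it is provided so the difference against
#' IOU-thresholded accuracy can be quantified.
#'
#' @param pred,gt [BoundingBox-class] objects.
#' @return Logical scalar.
#' @export
centerCriterion <- function(pred, gt) {
  d <- sqrt(sum((boxCenter(pred) - boxCenter(gt))^2))
  d < max(boxWidth(gt), boxHeight(gt))
}

#' Evaluate localization predictions against ground truth
#'
#' The IOU protocol: per-image IOU and coverage fraction, accuracy at each
#' IOU threshold (`100 * #(IOU > t) / n`, strict inequality), the weak
#' centre criterion rate, and mean IOU / mean coverage (both reported,
#' since "average overlap" is quoted ambiguously between the two in the
#' literature).  Ground-truth images without a prediction are counted
#' incorrect (IOU 0) and listed in `missing`.
#'
#' @param preds,gts annotation data frames (see [annotationRecord()]);
#'   every `gts$image_id` should have a prediction.
#' @param thresholds IOU thresholds, ratios in `(0, 1)`.
#' @return A list of class `LocalizationReport`: `per_image` data frame
#'   (`image_id, iou, coverage_frac, center_ok`, one `correct_at_*` column
#'   per threshold), `accuracy_at` (named percent vector), `mean_iou`,
#'   `mean_coverage`, `center_criterion_pct` (percents), `n`, `missing`.
#' @examples
#' gt <- annotationRecord("a", boundingBox(0, 0, 10, 10))
#' pr <- annotationRecord("a", boundingBox(5, 0, 15, 10))
#' evaluateLocalization(pr, gt, thresholds = c(0.2, 0.5))$accuracy_at
#' @export
evaluateLocalization <- function(preds, gts,
                                 thresholds = c(0.2, 0.5, 0.6, 0.7, 0.8)) {
  if (is.null(gts) || nrow(gts) == 0L) stop("empty ground-truth set")
  stopifnot(all(thresholds > 0), all(thresholds < 1))
  validateAnnotations(gts, "ground truth")
  if (nrow(preds)) validateAnnotations(preds, "predictions")
  missing <- setdiff(gts$image_id, preds$image_id)
  if (length(missing)) {
    logMsg("WARNING", sprintf("no prediction for %d image(s): %s",
                              length(missing),
                              paste(missing, collapse = ", ")))
  }
  rowBox <- function(df, i) boundingBox(df$x_min[i], df$y_min[i],
                                        df$x_max[i], df$y_max[i])
  n <- nrow(gts)
  ious <- cov <- numeric(n)
  cen <- logical(n)
  for (i in seq_len(n)) {
    j <- match(gts$image_id[i], preds$image_id)
    if (is.na(j)) next
    p <- rowBox(preds, j); g <- rowBox(gts, i)
    ious[i] <- iou(p, g)
    cov[i] <- coverageFraction(p, g)
    cen[i] <- centerCriterion(p, g)
  }
  perImage <- data.frame(image_id = gts$image_id, iou = ious,
                         coverage_frac = cov, center_ok = cen,
                         stringsAsFactors = FALSE)
  accuracyAt <- vapply(thresholds, function(t) 100 * mean(ious > t), 0)
  names(accuracyAt) <- format(thresholds)
  for (t in seq_along(thresholds)) {
    perImage[[sprintf("correct_at_%s", format(thresholds[t]))]] <-
      ious > thresholds[t]
  }
  structure(list(per_image = perImage, accuracy_at = accuracyAt,
                 mean_iou = 100 * mean(ious), mean_coverage = 100 * mean(cov),
                 center_criterion_pct = 100 * mean(cen),
                 n = n, missing = missing),
            class = "LocalizationReport")
}

#' @export
print.LocalizationReport <- function(x, ...) {
  cat(sprintf("LocalizationReport over %d image(s)\n", x$n))
  cat("  accuracy at IOU >",
      paste(sprintf("%s: %.2f%%", names(x$accuracy_at), x$accuracy_at),
            collapse = ", "), "\n")
  cat(sprintf("  mean IOU %.2f%%, mean coverage %.2f%%, centre criterion %.2f%%\n",
              x$mean_iou, x$mean_coverage, x$center_criterion_pct))
  if (length(x$missing)) {
    cat("  missing predictions:", length(x$missing), "\n")
  }
  invisible(x)
}

#' Write a localization report as JSON
#'
#' @param report a `LocalizationReport` from [evaluateLocalization()].
#' @param path output file.
#' @return The path, invisibly.
#' @export
writeLocalizationReport <- function(report, path) {
  out <- unclass(report)
  out$accuracy_at <- as.list(out$accuracy_at)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
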