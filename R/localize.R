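#' Configuration of the rule-based optic-disc localizer
#'
#' All tunables of the localization pipeline.  The working size fixes the
#' scale every image is processed at (results are mapped back to the original
#' frame); `cropMarginFrac` shrinks the estimated retina circle before
#' masking so a thin bright fringe at the rim is discarded; `topBrightFrac`
#' is the fraction of brightest pixels whose mean defines the adaptive
#' binarization threshold; erosion/dilation radii are disc structuring
#' elements at the working scale; `proposalScale > 1` enlarges the measured
#' blob radius into the proposed disc circle.
#'
#' @param workingSize processing scale in pixels (square).
#' @param cropMarginFrac fraction of the retina radius kept, in `(0, 1)`.
#' @param topBrightFrac fraction of brightest non-zero pixels averaged into
#'   the adaptive threshold.
#' @param erodeRadius,dilateRadius disc structuring-element radii, pixels.
#' @param proposalScale multiplier `> 1` applied to the measured blob radius.
#' @param minBlobArea blobs smaller than this (pixels^2) are ignored.
#' @param maxRadiusFrac optional sanity bound: proposals with radius above
#'   this fraction of the retina radius are rejected (fallback path);
#'   `NULL` disables it.
#' @return A validated list of class `HeuristicConfig`.
#' @export
heuristicConfig <- function(workingSize = 1500, cropMarginFrac = 0.95,
                            topBrightFrac = 0.01, erodeRadius = 4,
                            dilateRadius = 10, proposalScale = 1.5,
                            minBlobArea = 25, maxRadiusFrac = NULL) {
  stopifnot(cropMarginFrac > 0, cropMarginFrac < 1,
            topBrightFrac > 0, topBrightFrac < 1,
            proposalScale > 1, workingSize >= 64,
            erodeRadius >= 0, dilateRadius >= 0, minBlobArea >= 0)
  if (!is.null(maxRadiusFrac)) stopifnot(maxRadiusFrac > 0)
  structure(list(workingSize = as.integer(workingSize),
                 cropMarginFrac = cropMarginFrac,
                 topBrightFrac = topBrightFrac,
                 erodeRadius = erodeRadius, dilateRadius = dilateRadius,
                 proposalScale = proposalScale, minBlobArea = minBlobArea,
                 maxRadiusFrac = maxRadiusFrac),
            class = "HeuristicConfig")
}

#' Estimate the retina circle by Otsu thresholding
#'
#' Otsu's method on the grayscale luminance largely turns the retina into a
#' white disc on a black background; the estimate is the centroid of that
#' foreground mask with radius `sqrt(area / pi)`.
#'
#' @param image a [FundusImage-class].
#' @return A [CircleProposal-class] for the retina.
#' @section Errors: if the foreground covers less than 1\% of the image the
#'   input is not a fundus photograph and a `"no retina found"` error is
#'   raised.
#' @export
estimateRetina <- function(image) {
  lum <- luminance(image)
  thr <- EBImage::otsu(t(lum) / 255, range = c(0, 1)) * 255
  # ">=" with a floor of 1 keeps degenerate all-bright frames as foreground
  # while an all-dark frame yields none at all
  fg <- lum >= max(thr, 1)
  area <- sum(fg)
  if (area < 0.01 * length(lum)) stop("no retina found")
  idx <- which(fg, arr.ind = TRUE)
  circleProposal(cx = mean(idx[, 2]) - 1, cy = mean(idx[, 1]) - 1,
                 r = sqrt(area / pi))
}

#' Crop away the retinal rim
#'
#' Applies a circular mask of radius `marginFrac * retina@r` (same centre):
#' pixels outside are set to 0, inside are unchanged.  A bright fringe at
#' the rim thinner than `1 - marginFrac` of the radius is removed entirely.
#'
#' @param image a [FundusImage-class].
#' @param retina retina [CircleProposal-class] from [estimateRetina()].
#' @param marginFrac fraction of the retina radius kept, in `(0, 1)`.
#' @return A masked [FundusImage-class].
#' @export
cropRim <- function(image, retina, marginFrac = 0.95) {
  stopifnot(marginFrac > 0, marginFrac < 1)
  d <- dim(image@pixels)
  x <- matrix(0:(d[2] - 1), d[1], d[2], byrow = TRUE)
  y <- matrix(0:(d[1] - 1), d[1], d[2])
  outside <- (x - retina@cx)^2 + (y - retina@cy)^2 >
    (marginFrac * retina@r)^2
  px <- image@pixels
  for (ch in 1:3) {
    plane <- px[, , ch]
    plane[outside] <- 0L
    px[, , ch] <- plane
  }
  fundusImage(px, image@imageId, image@originalSize)
}

#' Adaptive binarization at the mean of the brightest pixels
#'
#' The threshold is the mean luminance of the brightest `topFrac` (default
#' 1\%) of non-zero pixels; the mask keeps pixels at or above it.  On fundus
#' input only the disc-core-like regions survive.
#'
#' @param image a [FundusImage-class] (typically rim-cropped).
#' @param topFrac fraction of brightest non-zero pixels averaged.
#' @return Logical `H x W` matrix.
#' @section Errors: fewer than 100 non-zero pixels raises
#'   `"image too dark"`.
#' @export
adaptiveBinarize <- function(image, topFrac = 0.01) {
  lum <- luminance(image)
  nz <- lum[lum > 0]
  if (length(nz) < 100) stop("image too dark")
  k <- max(1L, ceiling(topFrac * length(nz)))
  thr <- mean(sort(nz, decreasing = TRUE)[seq_len(k)])
  lum >= thr
}

#' Morphological cleanup of a binary mask
#'
#' Erosion with a disc structuring element (removing small reflective areas
#' and impulse noise) followed by dilation with a disc (reconnecting
#' disjoint bright spots into fewer, bigger blobs).  Radius 0 skips the
#' corresponding operation.
#'
#' @param mask logical `H x W` matrix.
#' @param erodeRadius,dilateRadius structuring-element radii in pixels.
#' @return Logical `H x W` matrix.
#' @export
cleanMask <- function(mask, erodeRadius = 4, dilateRadius = 10) {
  stopifnot(erodeRadius >= 0, dilateRadius >= 0)
  m <- t(mask * 1)
  if (erodeRadius > 0) {
    m <- EBImage::erode(m, EBImage::makeBrush(2 * round(erodeRadius) + 1,
                                              "disc"))
  }
  if (dilateRadius > 0) {
    m <- EBImage::dilate(m, EBImage::makeBrush(2 * round(dilateRadius) + 1,
                                               "disc"))
  }
  t(m) > 0.5
}

#' Propose the optic-disc circle from a cleaned mask
#'
#' Selects the largest connected component by pixel area (ties broken by the
#' smaller `(y, x)` centroid), takes its centroid as the centre and
#' `sqrt(area / pi)` as the raw radius, and returns a circle enlarged by
#' `proposalScale`.
#'
#' @param mask logical `H x W` matrix.
#' @param config a [heuristicConfig()].
#' @return A [CircleProposal-class].
#' @section Errors: an empty mask (or none of the components reaching
#'   `minBlobArea`) raises `"no disc candidate"`; [localizeDisc()] catches
#'   this and falls back to the brightest-pixel centroid.
#' @export
proposeOD <- function(mask, config = heuristicConfig()) {
  lab <- t(EBImage::bwlabel(t(mask * 1)))
  nLab <- max(lab)
  if (nLab < 1) stop("no disc candidate")
  areas <- tabulate(lab[lab > 0], nbins = nLab)
  keep <- which(areas >= config$minBlobArea)
  if (!length(keep)) stop("no disc candidate")
  idx <- which(lab > 0, arr.ind = TRUE)
  labv <- lab[idx]
  cy <- vapply(keep, function(l) mean(idx[labv == l, 1]) - 1, 0)
  cx <- vapply(keep, function(l) mean(idx[labv == l, 2]) - 1, 0)
  ord <- order(-areas[keep], cy, cx)
  best <- ord[1]
  circleProposal(cx = cx[best], cy = cy[best],
                 r = config$proposalScale * sqrt(areas[keep[best]] / pi))
}

# Fallback when no blob survives cleanup: centroid of the brightest
# topBrightFrac pixels, radius a tenth of the retina radius.
brightestFallback <- function(image, retina, config) {
  lum <- luminance(image)
  nz <- which(lum > 0)
  k <- max(1L, ceiling(config$topBrightFrac * length(nz)))
  top <- nz[order(lum[nz], decreasing = TRUE)[seq_len(k)]]
  iy <- (top - 1) %% nrow(lum) + 1
  ix <- (top - 1) %/% nrow(lum) + 1
  circleProposal(cx = mean(ix) - 1, cy = mean(iy) - 1,
                 r = max(1, 0.1 * retina@r))
}

#' Localize the optic disc in a fundus image
#'
#' The full rule-based pipeline: rescale to the working size, estimate the
#' retina by Otsu thresholding, crop the rim, adaptively binarize at the
#' top-1\%-mean threshold, clean the mask morphologically, propose the
#' largest-blob circle, and map the circle back to the image's original
#' frame (independent x/y scale factors).  The returned box is the tight
#' square box of the circle clipped to the image bounds.
#'
#' If no disc candidate survives cleanup the proposal falls back to the
#' centroid of the brightest pixels and the record is flagged low-confidence.
#'
#' @param image a [FundusImage-class].
#' @param config a [heuristicConfig()].
#' @return A list of class `ODLocalization`: `circle`
#'   ([CircleProposal-class], original frame), `box` ([BoundingBox-class]),
#'   `confidence` (`"normal"` or `"low"`), `status` (`"proposed"`), and
#'   `imageId`.
#' @examples
#' res <- generateImage(syntheticSpec(imageSize = 300, seed = 3))
#' loc <- localizeDisc(res$image, heuristicConfig(workingSize = 300))
#' iou(loc$box, res$gt@odBox)
#' @export
localizeDisc <- function(image, config = heuristicConfig()) {
  origH <- nrow(image@pixels); origW <- ncol(image@pixels)
  work <- resizeFundus(image, config$workingSize, config$workingSize)
  retina <- estimateRetina(work)
  cropped <- cropRim(work, retina, config$cropMarginFrac)
  mask <- adaptiveBinarize(cropped, config$topBrightFrac)
  mask <- cleanMask(mask, config$erodeRadius, config$dilateRadius)
  confidence <- "normal"
  circle <- tryCatch(proposeOD(mask, config), error = function(e) NULL)
  if (!is.null(circle) && !is.null(config$maxRadiusFrac) &&
      circle@r > config$maxRadiusFrac * retina@r) {
    circle <- NULL
  }
  if (is.null(circle)) {
    circle <- brightestFallback(cropped, retina, config)
    confidence <- "low"
    logMsg("WARNING", sprintf(
      "%s: no disc candidate; brightest-pixel fallback used", image@imageId),
      verbose = FALSE)
  }
  sx <- origW / config$workingSize
  sy <- origH / config$workingSize
  mapped <- circleProposal(cx = circle@cx * sx, cy = circle@cy * sy,
                           r = circle@r * sqrt(sx * sy))
  box <- circleToBox(mapped, origH, origW)
  structure(list(circle = mapped, box = box, confidence = confidence,
                 status = "proposed", imageId = image@imageId),
            class = "ODLocalization")
}

#' @export
print.ODLocalization <- function(x, ...) {
  cat(sprintf("ODLocalization '%s': centre (%.1f, %.1f) r %.1f, %s confidence\n",
              x$imageId, x$circle@cx, x$circle@cy, x$circle@r, x$confidence))
  invisible(x)
}
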