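#' FundusImage: an RGB retinal fundus raster
#'
#' The unit every stage of the toolkit consumes: an 8-bit RGB raster with an
#' identity and a record of the size it was originally acquired at (localization
#' results are always mapped back to that frame).
#'
#' Pixels are stored as an integer array of dimension `H x W x 3` with values
#' in `[0, 255]`; the first index is the image row (y, downward), the second the
#' column (x, rightward).  Continuous pixel coordinates are 0-based so that the
#' centre of the top-left pixel is `(x = 0, y = 0)`.
#'
#' @slot pixels integer array, `H x W x 3`, values in 0..255.
#' @slot imageId single character identifier.
#' @slot originalSize integer length-2 `(H, W)` of the acquisition frame.
#'
#' @seealso [fundusImage()], [readFundus()], [writeFundus()]
#' @export
setClass("FundusImage",
  representation(pixels = "array", imageId = "character",
                 originalSize = "integer"),
  validity = function(object) {
    d <- dim(object@pixels)
    if (length(d) != 3L || d[3] != 3L)
      return("pixels must be an H x W x 3 array")
    if (d[1] < 32L || d[2] < 32L)
      return("image must be at least 32 x 32 pixels")
    if (anyNA(object@pixels)) return("pixels contain NA")
    rng <- range(object@pixels)
    if (rng[1] < 0 || rng[2] > 255) return("pixel values must lie in [0, 255]")
    if (length(object@imageId) != 1L) return("imageId must be a single string")
    if (length(object@originalSize) != 2L || any(object@originalSize < 1L))
      return("originalSize must be positive (H, W)")
    TRUE
  })

#' CircleProposal: a circular optic-disc (or retina) location hypothesis
#'
#' Continuous 0-based centre coordinates (`x` rightward, `y` downward) and a
#' positive radius, all in pixels.  The rule-based localizer's native output.
#'
#' @slot cx,cy numeric centre coordinates in pixels.
#' @slot r numeric radius in pixels, strictly positive.
#' @export
setClass("CircleProposal",
  representation(cx = "numeric", cy = "numeric", r = "numeric"),
  validity = function(object) {
    if (any(lengths(list(object@cx, object@cy, object@r)) != 1L))
      return("cx, cy, r must be scalars")
    if (!is.finite(object@r) || object@r <= 0) return("r must be > 0")
    if (!is.finite(object@cx) || !is.finite(object@cy))
      return("centre must be finite")
    TRUE
  })

#' BoundingBox: an axis-aligned box in half-open pixel coordinates
#'
#' Integer, 0-based, half-open convention: the box covers the pixel grid
#' `[x_min, x_max) x [y_min, y_max)`, so its area is
#' `(x_max - x_min) * (y_max - y_min)` pixels.  This is the ground-truth and
#' evaluation currency of the toolkit; conversion to 1-based inclusive
#' coordinates happens only at the Pascal-VOC XML boundary.
#'
#' @slot xMin,yMin,xMax,yMax integer pixel coordinates, `xMin < xMax`,
#'   `yMin < yMax`.
#' @export
setClass("BoundingBox",
  representation(xMin = "integer", yMin = "integer",
                 xMax = "integer", yMax = "integer"),
  validity = function(object) {
    v <- c(object@xMin, object@yMin, object@xMax, object@yMax)
    if (length(v) != 4L || anyNA(v)) return("box coordinates must be scalars")
    if (object@xMin >= object@xMax) return("x_min must be < x_max")
    if (object@yMin >= object@yMax) return("y_min must be < y_max")
    TRUE
  })

#' SyntheticSpec: full parametric description of one synthetic fundus scene
#'
#' Everything needed to render one fundus-like image deterministically:
#' geometry of retina, optic disc (OD) and cup, intensity levels, vessel and
#' artifact settings, noise and the seed.  Identical specs (including the
#' seed) render bit-identical images.
#'
#' The noise-free scene respects the intensity ordering
#' `backgroundLevel < retinaLevel < odBrightness <= cupBrightness`, the OD
#' ellipse lies entirely inside the retina circle and the cup (radius
#' `cdr * od radius`) entirely inside the OD.
#'
#' @slot imageSize integer side of the square image in pixels.
#' @slot retinaRadiusFrac retina radius as a fraction of half-width, in
#'   `(0.7, 1]`.
#' @slot retinaCenterJitter numeric length-2 `(dx, dy)` offset of the retina
#'   centre from the image centre, pixels.
#' @slot odEccentricity,odAngle polar OD position within the retina:
#'   eccentricity as a fraction in `[0, 1)` of the largest offset that keeps
#'   the OD inside the retina, and angle in radians.
#' @slot odRadiusFrac OD radius as a fraction of the retina radius, in
#'   `[0.05, 0.15]`.
#' @slot odAxisRatio ratio of the OD ellipse's x to y semi-axis, around 1.
#' @slot cdr cup-to-disc diameter ratio in `[0.2, 0.95]`.
#' @slot cupPallor chromatic pallor of the cup: green/blue boost (red
#'   reduced to keep luminance constant) inside the cup, in intensity units.
#' @slot odBrightness,cupBrightness,backgroundLevel,retinaLevel intensity
#'   levels in `[0, 255]` of the scene's value channel.
#' @slot nVessels number of vessels radiating from the OD.
#' @slot vesselDarkness intensity subtracted along vessels.
#' @slot vesselWidth maximum vessel width in pixels at the 1500 scale.
#' @slot fringe `"none"` or `"arc"`: bright fringe at the retinal rim.
#' @slot fringeExtent,fringeBrightness,fringeThicknessFrac arc extent in
#'   degrees, peak intensity, and annulus thickness as a fraction of the
#'   retina radius.
#' @slot nReflections count of bright cloud-like reflection blobs.
#' @slot reflectionSigma,reflectionPeak numeric length-2 ranges for per-blob
#'   Gaussian sigma (pixels) and peak intensity.
#' @slot noiseSigma standard deviation of additive Gaussian noise.
#' @slot channelMix numeric length-3 multipliers mapping the value channel to
#'   (R, G, B); red-dominant by default.
#' @slot seed integer RNG seed for noise, vessels and artifact placement.
#' @seealso [syntheticSpec()], [generateImage()]
#' @export
setClass("SyntheticSpec",
  representation(imageSize = "integer", retinaRadiusFrac = "numeric",
                 retinaCenterJitter = "numeric",
                 odEccentricity = "numeric", odAngle = "numeric",
                 odRadiusFrac = "numeric", odAxisRatio = "numeric",
                 cdr = "numeric", cupPallor = "numeric",
                 odBrightness = "numeric", cupBrightness = "numeric",
                 backgroundLevel = "numeric", retinaLevel = "numeric",
                 nVessels = "integer", vesselDarkness = "numeric",
                 vesselWidth = "numeric",
                 fringe = "character", fringeExtent = "numeric",
                 fringeBrightness = "numeric", fringeThicknessFrac = "numeric",
                 nReflections = "integer", reflectionSigma = "numeric",
                 reflectionPeak = "numeric",
                 noiseSigma = "numeric", channelMix = "numeric",
                 seed = "integer"),
  validity = function(object) {
    chk <- function(cond, msg) if (!cond) msg else NULL
    probs <- c(
      chk(object@imageSize >= 64L, "imageSize: must be >= 64"),
      chk(object@retinaRadiusFrac > 0.7 && object@retinaRadiusFrac <= 1,
          "retinaRadiusFrac: must lie in (0.7, 1]"),
      chk(length(object@retinaCenterJitter) == 2L,
          "retinaCenterJitter: must be length 2"),
      chk(object@odEccentricity >= 0 && object@odEccentricity < 1,
          "odEccentricity: must lie in [0, 1)"),
      chk(object@odRadiusFrac >= 0.05 && object@odRadiusFrac <= 0.15,
          "odRadiusFrac: must lie in [0.05, 0.15]"),
      chk(object@odAxisRatio >= 0.8 && object@odAxisRatio <= 1.25,
          "odAxisRatio: must lie in [0.8, 1.25]"),
      chk(object@cdr >= 0.2 && object@cdr <= 0.95,
          "cdr: must lie in [0.2, 0.95]"),
      chk(object@cupPallor >= 0 && object@cupPallor <= 60,
          "cupPallor: must lie in [0, 60]"),
      chk(object@backgroundLevel >= 0 && object@cupBrightness <= 255,
          "intensity levels must lie in [0, 255]"),
      chk(object@backgroundLevel < object@retinaLevel,
          "backgroundLevel: must be < retinaLevel"),
      chk(object@retinaLevel < object@odBrightness,
          "retinaLevel: must be < odBrightness"),
      chk(object@odBrightness <= object@cupBrightness,
          "odBrightness: must be <= cupBrightness"),
      chk(object@nVessels >= 0L, "nVessels: must be >= 0"),
      chk(object@vesselDarkness >= 0, "vesselDarkness: must be >= 0"),
      chk(object@fringe %in% c("none", "arc"),
          "fringe: must be 'none' or 'arc'"),
      chk(object@fringe == "none" || object@fringeExtent > 0,
          "fringeExtent: must be > 0 for an arc fringe"),
      chk(object@fringeThicknessFrac > 0 && object@fringeThicknessFrac < 0.3,
          "fringeThicknessFrac: must lie in (0, 0.3)"),
      chk(object@nReflections >= 0L, "nReflections: must be >= 0"),
      chk(object@noiseSigma >= 0, "noiseSigma: must be >= 0"),
      chk(length(object@channelMix) == 3L && all(object@channelMix > 0) &&
            all(object@channelMix <= 1),
          "channelMix: must be 3 multipliers in (0, 1]"),
      chk(length(object@seed) == 1L && !is.na(object@seed),
          "seed: must be a single integer")
    )
    if (length(probs)) probs[[1]] else TRUE
  })

#' GroundTruth: exact annotation attached to a generated image
#'
#' The tight axis-aligned box of the rendered OD ellipse, the circumscribing
#' circle, the class label derived from the cup-to-disc ratio, and the ratio
#' itself.
#'
#' @slot odBox [BoundingBox-class] tight box of the OD ellipse.
#' @slot odCircle [CircleProposal-class] circumscribing circle of the OD.
#' @slot label `"healthy"` or `"glaucoma"`; glaucoma iff
#'   `cdr > labelThreshold`.
#' @slot cdr the cup-to-disc diameter ratio of the scene.
#' @slot labelThreshold the CDR cut-off used to assign the label.
#' @export
setClass("GroundTruth",
  representation(odBox = "BoundingBox", odCircle = "CircleProposal",
                 label = "character", cdr = "numeric",
                 labelThreshold = "numeric"),
  validity = function(object) {
    if (!object@label %in% c("healthy", "glaucoma"))
      return("label must be 'healthy' or 'glaucoma'")
    want <- if (object@cdr > object@labelThreshold) "glaucoma" else "healthy"
    if (object@label != want)
      return("label inconsistent with cdr and labelThreshold")
    TRUE
  })

#' ConfusionCounts: per-class confusion-matrix tallies
#'
#' Holds the full truth-by-prediction contingency table; per-class
#' true/false positive/negative counts are derived views of it, so the
#' binary complementarity identities (e.g. TP of one class = TN of the
#' other) hold by construction.
#'
#' @slot table integer matrix, rows = true class, columns = predicted class.
#' @slot classes character vector of class names (row/column order).
#' @seealso [confusionCounts()], [truePositives()]
#' @export
setClass("ConfusionCounts",
  representation(table = "matrix", classes = "character"),
  validity = function(object) {
    if (nrow(object@table) != ncol(object@table))
      return("table must be square")
    if (length(object@classes) != nrow(object@table))
      return("classes must match table dimension")
    if (any(object@table < 0)) return("counts must be non-negative")
    TRUE
  })
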