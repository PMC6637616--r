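#' Construct a BoundingBox
#'
#' 0-based, half-open convention: the box covers pixels with integer
#' coordinates `x` in `[xMin, xMax)` and `y` in `[yMin, yMax)`.
#'
#' @param xMin,yMin,xMax,yMax integer pixel coordinates.
#' @return A [BoundingBox-class].
#' @examples
#' b <- boundingBox(0, 0, 10, 10)
#' boxArea(b)  # 100
#' @export
boundingBox <- function(xMin, yMin, xMax, yMax) {
  new("BoundingBox", xMin = as.integer(xMin), yMin = as.integer(yMin),
      xMax = as.integer(xMax), yMax = as.integer(yMax))
}

#' Construct a CircleProposal
#'
#' @param cx,cy continuous 0-based centre coordinates (x rightward, y
#'   downward), pixels.
#' @param r radius in pixels, `> 0`.
#' @return A [CircleProposal-class].
#' @export
circleProposal <- function(cx, cy, r) {
  new("CircleProposal", cx = as.numeric(cx), cy = as.numeric(cy),
      r = as.numeric(r))
}

setMethod("show", "BoundingBox", function(object) {
  cat(sprintf("BoundingBox [%d, %d) x [%d, %d)  (%d x %d px)\n",
              object@xMin, object@xMax, object@yMin, object@yMax,
              object@xMax - object@xMin, object@yMax - object@yMin))
})

setMethod("show", "CircleProposal", function(object) {
  cat(sprintf("CircleProposal centre (%.1f, %.1f), r = %.1f px\n",
              object@cx, object@cy, object@r))
})

#' Box geometry helpers
#'
#' `boxArea` is the pixel area under the half-open convention; `boxCenter`
#' the continuous centre `(x, y)`; `boxWidth`/`boxHeight` the side lengths.
#'
#' @param box a [BoundingBox-class].
#' @return numeric scalar (or length-2 vector for `boxCenter`).
#' @export
boxArea <- function(box) {
  as.numeric(box@xMax - box@xMin) * as.numeric(box@yMax - box@yMin)
}

#' @rdname boxArea
#' @export
boxCenter <- function(box) {
  c(x = (box@xMin + box@xMax) / 2 - 0.5, y = (box@yMin + box@yMax) / 2 - 0.5)
}

#' @rdname boxArea
#' @export
boxWidth <- function(box) as.numeric(box@xMax - box@xMin)

#' @rdname boxArea
#' @export
boxHeight <- function(box) as.numeric(box@yMax - box@yMin)

# Half-open integer box covering the continuous extent [lo, hi] on one axis:
# all pixels whose centres (integer coordinates) fall inside the extent.
extentToRange <- function(lo, hi, limit) {
  c(max(0, ceiling(lo)), min(limit, floor(hi) + 1))
}

#' Tight square box of a circle
#'
#' The half-open box containing every pixel whose centre lies within the
#' circle's axis extents, clipped to the image bounds.
#'
#' @param circle a [CircleProposal-class].
#' @param height,width image bounds used for clipping, pixels.
#' @return A [BoundingBox-class].
#' @export
circleToBox <- function(circle, height, width) {
  xr <- extentToRange(circle@cx - circle@r, circle@cx + circle@r, width)
  yr <- extentToRange(circle@cy - circle@r, circle@cy + circle@r, height)
  boundingBox(xr[1], yr[1], xr[2], yr[2])
}

# Tight box of an axis-aligned ellipse, clipped to image bounds.
ellipseToBox <- function(cx, cy, a, b, height, width) {
  xr <- extentToRange(cx - a, cx + a, width)
  yr <- extentToRange(cy - b, cy + b, height)
  boundingBox(xr[1], yr[1], xr[2], yr[2])
}
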