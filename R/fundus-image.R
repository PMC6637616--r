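#' Construct a FundusImage
#'
#' @param pixels numeric or integer `H x W x 3` array with values in
#'   `[0, 255]` (or a `H x W` matrix, replicated over 3 channels).
#' @param imageId identifier string.
#' @param originalSize integer `(H, W)`; defaults to the array's own size.
#' @return A [FundusImage-class] object.
#' @examples
#' img <- fundusImage(array(100L, c(64, 64, 3)), "toy")
#' imageSize(img)
#' @export
fundusImage <- function(pixels, imageId = "image",
                        originalSize = dim(pixels)[1:2]) {
  if (is.matrix(pixels)) pixels <- array(pixels, c(dim(pixels), 3L))
  storage.mode(pixels) <- "integer"
  new("FundusImage", pixels = pixels, imageId = as.character(imageId),
      originalSize = as.integer(originalSize))
}

#' @describeIn fundusImage The pixel array of an image.
#' @param x a `FundusImage`.
#' @export
imagePixels <- function(x) x@pixels

#' @describeIn fundusImage The image identifier.
#' @export
imageId <- function(x) x@imageId

#' @describeIn fundusImage `(H, W)` of the pixel array.
#' @export
imageSize <- function(x) dim(x@pixels)[1:2]

#' @describeIn fundusImage `(H, W)` of the original acquisition frame.
#' @export
originalSize <- function(x) x@originalSize

setMethod("show", "FundusImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("FundusImage '%s': %d x %d x 3 (original %d x %d)\n",
              object@imageId, d[1], d[2],
              object@originalSize[1], object@originalSize[2]))
})

#' Grayscale luminance of a fundus image
#'
#' Standard Rec. 601 luminance `0.299 R + 0.587 G + 0.114 B`, the channel the
#' rule-based localizer thresholds on.
#'
#' @param image a [FundusImage-class] or an `H x W x 3` array.
#' @return Numeric `H x W` matrix in `[0, 255]`.
#' @export
luminance <- function(image) {
  px <- if (is(image, "FundusImage")) image@pixels else image
  0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]
}

# EBImage stores rasters transposed (x, y[, c]); these two helpers convert.
toEB <- function(a) {
  if (length(dim(a)) == 3L) aperm(a, c(2L, 1L, 3L)) else t(a)
}
fromEB <- function(a) {
  a <- unclass(a)
  if (length(dim(a)) == 3L) aperm(a, c(2L, 1L, 3L)) else t(a)
}

#' Resize a fundus image
#'
#' Bilinear interpolation (EBImage), matching the localizer's
#' fixed-working-size round-trip.  `originalSize` metadata is preserved.
#'
#' @param image a [FundusImage-class].
#' @param height,width target size in pixels.
#' @return A [FundusImage-class] of the requested size.
#' @export
resizeFundus <- function(image, height, width = height) {
  d <- dim(image@pixels)
  if (d[1] == height && d[2] == width) return(image)
  eb <- EBImage::Image(toEB(image@pixels / 255), colormode = "Color")
  out <- EBImage::resize(eb, w = width, h = height, filter = "bilinear")
  px <- clamp(roundHalfUp(fromEB(out) * 255), 0, 255)
  fundusImage(px, image@imageId, originalSize = image@originalSize)
}

# Nearest-neighbour resize for binary masks.
resizeMask <- function(mask, height, width = height) {
  out <- EBImage::resize(EBImage::Image(t(mask * 1)), w = width, h = height,
                         filter = "none")
  fromEB(out) > 0.5
}

#' Read / write fundus images as PNG
#'
#' @param path file path.
#' @param imageId identifier; defaults to the file name without extension.
#' @return `readFundus` returns a [FundusImage-class]; `writeFundus` the path,
#'   invisibly.
#' @export
readFundus <- function(path, imageId = sub("\\.[^.]+$", "", basename(path))) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 2L) a <- array(a, c(dim(a), 3L))
  if (dim(a)[3] == 4L) a <- a[, , 1:3, drop = FALSE]
  if (dim(a)[3] == 1L) a <- array(a[, , 1], c(dim(a)[1:2], 3L))
  fundusImage(roundHalfUp(a * 255), imageId)
}

#' @rdname readFundus
#' @param image a [FundusImage-class] to write.
#' @export
writeFundus <- function(image, path) {
  png::writePNG(image@pixels / 255, path)
  invisible(path)
}
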