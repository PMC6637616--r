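test_that("retina estimation recovers centre and radius within 2%", {
  sp <- syntheticSpec(imageSize = 600, retinaRadiusFrac = 280 / 300,
                      retinaCenterJitter = c(5, -8), seed = 2)
  res <- generateImage(sp)
  est <- estimateRetina(res$image)
  expect_lt(abs(est@cx - (299.5 + 5)) / 280, 0.02)
  expect_lt(abs(est@cy - (299.5 - 8)) / 280, 0.02)
  expect_lt(abs(est@r - 280) / 280, 0.02)
})

test_that("degenerate frames: all-black errors, all-white covers the frame", {
  black <- fundusImage(array(0L, c(64, 64, 3)), "black")
  expect_error(estimateRetina(black), "no retina found")
  white <- fundusImage(array(255L, c(64, 80, 3)), "white")
  est <- estimateRetina(white)
  expect_equal(est@r, sqrt(64 * 80 / pi), tolerance = 1e-6)
})

test_that("rim cropping removes a thin fringe and never adds intensity", {
  res <- smallScene()
  retina <- estimateRetina(res$image)
  fringed <- addFringe(res$image, retina, extent = 360, brightness = 250,
                       seed = 3, thicknessFrac = 0.03)
  cropped <- cropRim(fringed, retina, marginFrac = 0.95)
  # fringe annulus (thickness 3% < 5% margin) is gone entirely
  x <- matrix(0:599, 600, 600, byrow = TRUE); y <- matrix(0:599, 600, 600)
  rad <- sqrt((x - retina@cx)^2 + (y - retina@cy)^2)
  ann <- rad <= retina@r & rad >= retina@r * 0.97
  expect_true(all(luminance(cropped)[ann] == 0))
  expect_lte(sum(imagePixels(cropped)), sum(imagePixels(fringed)))
  # pixels inside the kept circle are untouched
  inside <- rad < 0.9 * retina@r
  expect_identical(imagePixels(cropped)[, , 1][inside],
                   imagePixels(fringed)[, , 1][inside])
})

test_that("adaptive binarization thresholds at the top-1% mean", {
  uni <- fundusImage(array(100L, c(100, 100, 3)), "uniform")
  m <- adaptiveBinarize(uni)
  expect_true(all(m))
  # 9900 pixels at 10 and 100 at 200: threshold is exactly 200
  px <- matrix(10, 100, 100)
  px[1:10, 1:10] <- 200
  img <- fundusImage(array(rep(px, 3), c(100, 100, 3)), "twolevel")
  m2 <- adaptiveBinarize(img)
  expect_identical(sum(m2), 100L)
  expect_true(all(which(m2) %in% which(px == 200)))
  dark <- fundusImage(array(0L, c(64, 64, 3)), "dark")
  expect_error(adaptiveBinarize(dark), "image too dark")
})

test_that("binarized core of a clean scene lies inside the ground-truth box", {
  for (seed in c(11, 31)) {
    res <- generateImage(syntheticSpec(imageSize = 600, seed = seed))
    retina <- estimateRetina(res$image)
    m <- adaptiveBinarize(cropRim(res$image, retina, 0.95))
    idx <- which(m, arr.ind = TRUE)
    bb <- res$gt@odBox
    expect_true(all(idx[, 2] - 1 >= bb@xMin & idx[, 2] - 1 < bb@xMax &
                      idx[, 1] - 1 >= bb@yMin & idx[, 1] - 1 < bb@yMax))
  }
})

test_that("morphological cleanup removes speckles and merges close blobs", {
  m <- matrix(FALSE, 80, 80)
  m[40, 40] <- TRUE                         # single-pixel speckle
  expect_false(any(cleanMask(m, erodeRadius = 2, dilateRadius = 0)))
  big <- matrix(FALSE, 80, 80)
  big[20:60, 20:60] <- TRUE
  expect_identical(cleanMask(big, 0, 0), big)
  # two blobs 10 px apart reconnect when the dilation reach covers the gap
  # plus what erosion stripped (dilate >= gap/2 + erode)
  two <- matrix(FALSE, 100, 100)
  two[40:60, 20:40] <- TRUE
  two[40:60, 51:70] <- TRUE
  lab0 <- EBImage::bwlabel(t(two * 1))
  expect_identical(max(lab0), 2L)
  merged <- cleanMask(two, erodeRadius = 2, dilateRadius = 8)
  expect_identical(max(EBImage::bwlabel(t(merged * 1))), 1L)
  # and a reach below that bound leaves them apart
  apart <- cleanMask(two, erodeRadius = 2, dilateRadius = 4)
  expect_identical(max(EBImage::bwlabel(t(apart * 1))), 2L)
})

test_that("disc proposal picks the largest blob and scales its radius", {
  m <- matrix(FALSE, 200, 200)
  x <- matrix(0:199, 200, 200, byrow = TRUE); y <- matrix(0:199, 200, 200)
  m[(x - 100)^2 + (y - 80)^2 <= 50^2] <- TRUE
  p <- proposeOD(m, heuristicConfig())
  expect_equal(p@cx, 100, tolerance = 0.05)
  expect_equal(p@cy, 80, tolerance = 0.05)
  expect_equal(p@r, 1.5 * 50, tolerance = 1)
  # largest of two components wins
  m[(x - 30)^2 + (y - 170)^2 <= 5^2] <- TRUE
  p2 <- proposeOD(m, heuristicConfig())
  expect_equal(p2@cx, 100, tolerance = 0.05)
  expect_error(proposeOD(matrix(FALSE, 50, 50), heuristicConfig()),
               "no disc candidate")
})

test_that("localization is equivariant to rescaling within 3% of width", {
  res <- generateImage(syntheticSpec(imageSize = 600, seed = 11))
  small <- resizeFundus(res$image, 360, 360)
  cfg <- smallConfig()
  l1 <- localizeDisc(res$image, cfg)
  l2 <- localizeDisc(small, cfg)
  dx <- l1$circle@cx - l2$circle@cx * 600 / 360
  dy <- l1$circle@cy - l2$circle@cy * 600 / 360
  expect_lt(sqrt(dx^2 + dy^2), 0.03 * 600)
})

test_that("an image without any bright disc takes the low-confidence fallback", {
  set.seed(9)
  S <- 300
  px <- matrix(8, S, S)
  x <- matrix(0:(S - 1), S, S, byrow = TRUE); y <- matrix(0:(S - 1), S, S)
  inside <- (x - 149.5)^2 + (y - 149.5)^2 <= 140^2
  px[inside] <- 90 + rnorm(sum(inside), 0, 5)
  img <- fundusImage(array(pmax(pmin(rep(px, 3), 255), 0), c(S, S, 3)),
                     "no-disc")
  loc <- localizeDisc(img, heuristicConfig(workingSize = 300))
  expect_identical(loc$confidence, "low")
  expect_identical(loc$status, "proposed")
  expect_s4_class(loc$box, "BoundingBox")
})

test_that("the optional maximum-radius sanity bound rejects huge proposals", {
  res <- smallScene()
  cfg <- heuristicConfig(workingSize = 600, maxRadiusFrac = 0.01)
  loc <- localizeDisc(res$image, cfg)
  expect_identical(loc$confidence, "low")
})
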