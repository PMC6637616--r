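test_that("identical specs render bit-identical images with consistent GT", {
  sp <- syntheticSpec(imageSize = 300, seed = 17)
  a <- generateImage(sp)
  b <- generateImage(sp)
  expect_identical(imagePixels(a$image), imagePixels(b$image))
  expect_equal(a$gt@odBox, b$gt@odBox)
  # the GT box is the tight box of the OD ellipse and contains its centre
  ctr <- boxCenter(a$gt@odBox)
  expect_true(abs(ctr["x"] - a$gt@odCircle@cx) < 1.5)
  expect_true(abs(ctr["y"] - a$gt@odCircle@cy) < 1.5)
})

test_that("class label follows the CDR threshold", {
  healthy <- generateImage(syntheticSpec(imageSize = 300, cdr = 0.30,
                                         seed = 1))
  sick <- generateImage(syntheticSpec(imageSize = 300, cdr = 0.80, seed = 1))
  expect_identical(healthy$gt@label, "healthy")
  expect_identical(sick$gt@label, "glaucoma")
  # boundary is strict: cdr equal to the threshold stays healthy
  at <- generateImage(syntheticSpec(imageSize = 300, cdr = 0.65, seed = 1))
  expect_identical(at$gt@label, "healthy")
})

test_that("noise-free artifact-free scene is brightest inside the OD box", {
  for (seed in c(2, 9, 23)) {
    sp <- syntheticSpec(imageSize = 400, noiseSigma = 0, seed = seed,
                        odEccentricity = 0.55, odAngle = seed)
    res <- generateImage(sp)
    lum <- luminance(res$image)
    idx <- which(lum == max(lum), arr.ind = TRUE)
    bb <- res$gt@odBox
    expect_true(all(idx[, 2] - 1 >= bb@xMin & idx[, 2] - 1 < bb@xMax))
    expect_true(all(idx[, 1] - 1 >= bb@yMin & idx[, 1] - 1 < bb@yMax))
  }
})

test_that("spec validation names the offending field", {
  expect_error(syntheticSpec(retinaLevel = 200, odBrightness = 150),
               "retinaLevel")
  expect_error(syntheticSpec(odBrightness = 240, cupBrightness = 230),
               "odBrightness")
  expect_error(syntheticSpec(odRadiusFrac = 0.3), "odRadiusFrac")
  expect_error(syntheticSpec(cdr = 0.1), "cdr")
})

test_that("mean OD-box intensity exceeds the rest of the retina on clean scenes", {
  ns <- 40
  seeds <- sample.int(1e6, ns)
  set.seed(123)
  ok <- logical(ns)
  for (i in seq_len(ns)) {
    lab <- if (i %% 4 == 0) "glaucoma" else "healthy"
    sp <- randomSpec(syntheticRanges(imageSize = 256), lab, seed = seeds[i])
    res <- generateImage(sp)
    lum <- luminance(res$image)
    bb <- res$gt@odBox
    inBox <- matrix(FALSE, nrow(lum), ncol(lum))
    inBox[(bb@yMin + 1):bb@yMax, (bb@xMin + 1):bb@xMax] <- TRUE
    S <- sp@imageSize
    gx <- matrix(0:(S - 1), S, S, byrow = TRUE)
    gy <- matrix(0:(S - 1), S, S)
    rcx <- (S - 1) / 2 + sp@retinaCenterJitter[1]
    rcy <- (S - 1) / 2 + sp@retinaCenterJitter[2]
    ret <- (gx - rcx)^2 + (gy - rcy)^2 <= (sp@retinaRadiusFrac * S / 2)^2
    ok[i] <- mean(lum[inBox]) > mean(lum[ret & !inBox])
  }
  expect_true(all(ok))
})

test_that("cup area fraction within the OD increases strictly with CDR", {
  areas <- vapply(c(0.3, 0.5, 0.7, 0.9), function(cdr) {
    sp <- syntheticSpec(imageSize = 300, cdr = cdr, noiseSigma = 0,
                        nVessels = 0, seed = 5)
    res <- generateImage(sp)
    lum <- luminance(res$image)
    # cup pixels sit above the step ring; count pixels above the midpoint
    sum(lum > max(lum) - 0.1 * (max(lum) - min(lum)))
  }, 0)
  expect_true(all(diff(areas) > 0))
})

test_that("generateDataset yields exact class counts and reproducible manifests", {
  r <- syntheticRanges(imageSize = 96)
  d1 <- generateDataset(40, ranges = r, glaucomaFraction = 0.25, seed = 5)
  expect_identical(sum(d1$manifest$label == "glaucoma"), 10L)
  expect_identical(nrow(d1$manifest), 40L)
  d2 <- generateDataset(40, ranges = r, glaucomaFraction = 0.25, seed = 5)
  expect_identical(d1$manifest, d2$manifest)
  # the reference-cohort balance: 650 draws at 168/650 give exactly 168
  n <- 650
  nG <- sum(rep(c("glaucoma", "healthy"),
                c(round(n * 168 / 650), n - round(n * 168 / 650))) ==
              "glaucoma")
  expect_identical(nG, 168L)
  expect_error(generateDataset(10, ranges = syntheticRanges(cdrHealthy = numeric(0))),
               "empty range")
  # labels in the manifest are consistent with the CDR threshold
  expect_true(all((d1$manifest$cdr > 0.65) ==
                    (d1$manifest$label == "glaucoma")))
})

test_that("dataset written to disk round-trips through PNG and CSV", {
  dir <- tempfile("synds")
  on.exit(unlink(dir, recursive = TRUE))
  r <- syntheticRanges(imageSize = 96)
  d <- generateDataset(3, ranges = r, glaucomaFraction = 1 / 3, seed = 8,
                       dir = dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_true(file.exists(file.path(dir, "specs.json")))
  man <- read.csv(file.path(dir, "manifest.csv"),
                  colClasses = c(image_id = "character"))
  expect_identical(nrow(man), 3L)
  img <- readFundus(man$path[1])
  ref <- generateImage(d$specs[[1]], imageId = man$image_id[1])
  expect_identical(imagePixels(img), imagePixels(ref$image))
})

test_that("fringe modifies only the rim annulus and never darkens", {
  res <- smallScene()
  retina <- circleProposal(299.5, 299.5, 0.94 * 300)
  out <- addFringe(res$image, retina, extent = 60, brightness = 250,
                   seed = 4, thicknessFrac = 0.03)
  dpx <- imagePixels(out) != imagePixels(res$image)
  idx <- which(dpx[, , 1] | dpx[, , 2] | dpx[, , 3], arr.ind = TRUE)
  expect_gt(nrow(idx), 0)
  rad <- sqrt((idx[, 2] - 1 - retina@cx)^2 + (idx[, 1] - 1 - retina@cy)^2)
  expect_true(all(rad <= retina@r + 1e-9))
  expect_true(all(rad >= retina@r * (1 - 0.03) - 1e-9))
  expect_gte(max(imagePixels(out)), max(imagePixels(res$image)))
  expect_error(addFringe(res$image, retina, extent = 0, brightness = 250),
               "extent")
  # full 360-degree arc touches the whole annulus
  full <- addFringe(res$image, retina, extent = 360, brightness = 250,
                    seed = 4, thicknessFrac = 0.03)
  lum0 <- luminance(res$image); lum1 <- luminance(full)
  x <- matrix(0:599, 600, 600, byrow = TRUE); y <- matrix(0:599, 600, 600)
  rr <- sqrt((x - retina@cx)^2 + (y - retina@cy)^2)
  ann <- rr <= retina@r & rr >= retina@r * 0.975
  expect_true(mean(lum1[ann] > lum0[ann]) > 0.99)
})

test_that("reflection blobs are reproducible and avoid the OD", {
  res <- smallScene()
  retina <- circleProposal(299.5, 299.5, 0.94 * 300)
  od <- res$gt@odCircle
  expect_identical(imagePixels(addReflections(res$image, retina, 0)),
                   imagePixels(res$image))
  a <- addReflections(res$image, retina, 3, seed = 9, avoid = od)
  b <- addReflections(res$image, retina, 3, seed = 9, avoid = od)
  expect_identical(attr(a, "blobs"), attr(b, "blobs"))
  blobs <- attr(a, "blobs")
  d <- sqrt((blobs[, "cx"] - od@cx)^2 + (blobs[, "cy"] - od@cy)^2)
  expect_true(all(d > od@r + 3 * blobs[, "sigma"]))
})
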