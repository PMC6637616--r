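#' Construct a SyntheticSpec
#'
#' Full parametric description of one synthetic fundus scene.  The defaults
#' describe a clean, realistic scene: a bright circular retina on a dark
#' background, a locally-brightest elliptical optic disc (OD) whose
#' intensity ramps up monotonically from the margin to the cup centre, a
#' chromatically pale cup whose diameter is `cdr` times the disc diameter,
#' and dark vessels radiating from the disc.  Artifacts (rim fringe,
#' reflection blobs) are off by default.
#'
#' @param imageSize side of the square image, pixels.
#' @param retinaRadiusFrac retina radius as fraction of half-width, `(0.7, 1]`.
#' @param retinaCenterJitter length-2 `(dx, dy)` pixels.
#' @param odEccentricity,odAngle polar OD position: fraction in `[0, 1)` of
#'   the largest centre offset that keeps the OD inside the retina, and angle
#'   in radians.
#' @param odRadiusFrac OD radius / retina radius, `[0.05, 0.15]`.
#' @param odAxisRatio x/y semi-axis ratio of the OD ellipse.
#' @param cdr cup-to-disc diameter ratio, `[0.2, 0.95]`.
#' @param cupPallor luminance-neutral whitening of the cup (green/blue
#'   boost, red reduced), intensity units.
#' @param odBrightness,cupBrightness,backgroundLevel,retinaLevel scene
#'   intensity levels, `background < retina < od <= cup`.
#' @param nVessels,vesselDarkness,vesselWidth vessel count, darkening, and
#'   maximum width (pixels at the 1500 scale).
#' @param fringe `"none"` or `"arc"`.
#' @param fringeExtent,fringeBrightness,fringeThicknessFrac arc extent
#'   (degrees), peak intensity, annulus thickness as fraction of retina radius.
#' @param nReflections,reflectionSigma,reflectionPeak reflection-blob count
#'   and per-blob sigma / peak ranges.
#' @param noiseSigma additive Gaussian noise standard deviation.
#' @param channelMix length-3 (R, G, B) multipliers of the value channel.
#' @param seed integer seed; identical specs render bit-identical images.
#' @return A validated [SyntheticSpec-class].
#' @examples
#' sp <- syntheticSpec(imageSize = 300, seed = 7)
#' res <- generateImage(sp)
#' res$gt@odBox
#' @export
syntheticSpec <- function(imageSize = 1500,
                          retinaRadiusFrac = 0.94,
                          retinaCenterJitter = c(0, 0),
                          odEccentricity = 0.5, odAngle = 0,
                          odRadiusFrac = 0.11, odAxisRatio = 1,
                          cdr = 0.4, cupPallor = 25,
                          odBrightness = 165, cupBrightness = 220,
                          backgroundLevel = 8, retinaLevel = 90,
                          nVessels = 8, vesselDarkness = 45, vesselWidth = 7,
                          fringe = c("none", "arc"), fringeExtent = 90,
                          fringeBrightness = 235, fringeThicknessFrac = 0.025,
                          nReflections = 0,
                          reflectionSigma = c(10, 25),
                          reflectionPeak = c(120, 190),
                          noiseSigma = 5,
                          channelMix = c(1, 0.56, 0.24),
                          seed = 1) {
  fringe <- match.arg(fringe)
  new("SyntheticSpec",
      imageSize = as.integer(imageSize),
      retinaRadiusFrac = retinaRadiusFrac,
      retinaCenterJitter = as.numeric(retinaCenterJitter),
      odEccentricity = odEccentricity, odAngle = odAngle,
      odRadiusFrac = odRadiusFrac, odAxisRatio = odAxisRatio,
      cdr = cdr, cupPallor = cupPallor,
      odBrightness = odBrightness, cupBrightness = cupBrightness,
      backgroundLevel = backgroundLevel, retinaLevel = retinaLevel,
      nVessels = as.integer(nVessels), vesselDarkness = vesselDarkness,
      vesselWidth = vesselWidth,
      fringe = fringe, fringeExtent = fringeExtent,
      fringeBrightness = fringeBrightness,
      fringeThicknessFrac = fringeThicknessFrac,
      nReflections = as.integer(nReflections),
      reflectionSigma = as.numeric(reflectionSigma),
      reflectionPeak = as.numeric(reflectionPeak),
      noiseSigma = noiseSigma, channelMix = as.numeric(channelMix),
      seed = as.integer(seed))
}

setMethod("show", "SyntheticSpec", function(object) {
  cat(sprintf(paste0("SyntheticSpec %d px, retina %.2f, OD frac %.3f ",
                     "(ecc %.2f @ %.2f rad), CDR %.2f, fringe %s, ",
                     "%d reflections, noise %.1f, seed %d\n"),
              object@imageSize, object@retinaRadiusFrac, object@odRadiusFrac,
              object@odEccentricity, object@odAngle, object@cdr,
              object@fringe, object@nReflections, object@noiseSigma,
              object@seed))
})

# Resolved scene geometry shared by the renderer and the ground truth.
specGeometry <- function(spec) {
  S <- spec@imageSize
  R <- spec@retinaRadiusFrac * S / 2
  rcx <- (S - 1) / 2 + spec@retinaCenterJitter[1]
  rcy <- (S - 1) / 2 + spec@retinaCenterJitter[2]
  rOD <- spec@odRadiusFrac * R
  a <- rOD * sqrt(spec@odAxisRatio)   # x semi-axis (area-preserving split)
  b <- rOD / sqrt(spec@odAxisRatio)   # y semi-axis
  maxOff <- R - max(a, b)
  off <- spec@odEccentricity * maxOff
  list(S = S, R = R, rcx = rcx, rcy = rcy, rOD = rOD, a = a, b = b,
       ox = rcx + off * cos(spec@odAngle), oy = rcy + off * sin(spec@odAngle))
}

# Stamp dark vessels as quadratic Bezier strips radiating from the OD
# centre toward the retinal rim; width tapers distally.  Returns a logical
# H x W mask.  Consumes RNG (caller seeds).
stampVessels <- function(S, g, n, widthMax) {
  mask <- matrix(FALSE, S, S)
  if (n < 1L) return(mask)
  wScale <- S / 1500                     # widths are quoted at the 1500 scale
  offs <- lapply(0:8, function(r) {
    d <- expand.grid(dx = -r:r, dy = -r:r)
    d[d$dx^2 + d$dy^2 <= r^2 + 0.5, , drop = FALSE]
  })
  angles <- runif(n, 0, 2 * pi)
  for (i in seq_len(n)) {
    phi <- angles[i]
    endR <- runif(1, 0.75, 0.95) * g$R
    p0 <- c(g$ox, g$oy)
    p2 <- c(g$rcx + endR * cos(phi), g$rcy + endR * sin(phi))
    v <- p2 - p0
    len <- sqrt(sum(v^2))
    perp <- c(-v[2], v[1]) / max(len, 1)
    p1 <- (p0 + p2) / 2 + runif(1, -0.25, 0.25) * len * perp
    nS <- max(24L, ceiling(len))
    t <- seq(0, 1, length.out = nS)
    bx <- (1 - t)^2 * p0[1] + 2 * (1 - t) * t * p1[1] + t^2 * p2[1]
    by <- (1 - t)^2 * p0[2] + 2 * (1 - t) * t * p1[2] + t^2 * p2[2]
    w0 <- runif(1, 0.55, 1) * widthMax * wScale
    ri <- pmax(0L, pmin(8L, as.integer(roundHalfUp(w0 * (1 - 0.65 * t) / 2))))
    ixc <- as.integer(roundHalfUp(bx)) + 1L   # 1-based column (x)
    iyc <- as.integer(roundHalfUp(by)) + 1L   # 1-based row (y)
    for (r in unique(ri)) {
      sel <- ri == r
      d <- offs[[r + 1L]]
      iy <- rep(iyc[sel], each = nrow(d)) + d$dy
      ix <- rep(ixc[sel], each = nrow(d)) + d$dx
      ok <- iy >= 1L & iy <= S & ix >= 1L & ix <= S
      mask[cbind(iy[ok], ix[ok])] <- TRUE
    }
  }
  mask
}

# Compose the value channel into an 8-bit RGB FundusImage.  `pallor` is an
# optional luminance-neutral chromatic shift (whitening): green and blue are
# raised and red lowered so that Rec. 601 luminance is unchanged.
valueToImage <- function(V, mix, imageId, pallor = NULL) {
  px <- array(0L, c(dim(V), 3L))
  shift <- list(0, 0, 0)
  if (!is.null(pallor)) {
    dg <- pallor; db <- 0.6 * pallor
    shift <- list(-(0.587 * dg + 0.114 * db) / 0.299, dg, db)
  }
  for (ch in 1:3) {
    px[, , ch] <- as.integer(clamp(roundHalfUp(V * mix[ch] + shift[[ch]]),
                                   0, 255))
  }
  fundusImage(px, imageId)
}

#' Render a synthetic fundus image with exact ground truth
#'
#' Deterministically renders the scene a [SyntheticSpec-class] describes and
#' returns the image together with its exact annotation: the tight bounding
#' box and circumscribing circle of the OD ellipse, the cup-to-disc ratio,
#' and the class label (`"glaucoma"` iff `cdr > labelThreshold`).
#'
#' The disc is rendered with a strictly monotone quadratic brightness ramp
#' from `odBrightness` at the rim to `cupBrightness` at the centre, a step
#' ring at the cup boundary, and a luminance-neutral chromatic pallor
#' (whitening) of the cup.  This gives the disc the bright sharp-edged core
#' structure that intensity-threshold localizers exploit, while the size of
#' the pale cup region carries the class signal.
#'
#' @param spec a [SyntheticSpec-class].
#' @param imageId identifier for the rendered image.
#' @param labelThreshold CDR cut-off separating healthy from glaucoma.
#' @return `list(image = FundusImage, gt = GroundTruth)`.
#' @export
generateImage <- function(spec, imageId = sprintf("syn-seed%d", spec@seed),
                          labelThreshold = 0.65) {
  stopifnot(validObject(spec))
  g <- specGeometry(spec)
  S <- g$S
  seeds <- deriveSeeds(spec@seed, 4L)

  x <- matrix(0:(S - 1), S, S, byrow = TRUE)
  y <- matrix(0:(S - 1), S, S)
  d2r <- (x - g$rcx)^2 + (y - g$rcy)^2
  retina <- d2r <= g$R^2

  V <- matrix(spec@backgroundLevel, S, S)
  V[retina] <- spec@retinaLevel

  u2 <- ((x - g$ox) / g$a)^2 + ((y - g$oy) / g$b)^2
  odMask <- u2 <= 1
  # strictly monotone radial profile: a quadratic ramp from odBrightness at
  # the disc margin to cupBrightness at the cup centre, plus a step ring at
  # the cup boundary.  The monotone ramp means intensity thresholds always
  # cut a solid, sharp-edged core (no flat plateau for noise to shred),
  # while the step ring at radius cdr carries the class signal
  delta <- spec@cupBrightness - spec@odBrightness
  profile <- spec@odBrightness + 0.8 * delta * (1 - u2) +
    0.2 * delta * (u2 <= spec@cdr^2)
  V[odMask] <- profile[odMask]

  vessels <- withSeed(seeds[1],
    stampVessels(S, g, spec@nVessels, spec@vesselWidth))
  dark <- vessels & retina
  V[dark] <- pmax(V[dark] - spec@vesselDarkness, spec@backgroundLevel)

  if (spec@noiseSigma > 0) {
    V <- V + withSeed(seeds[2], matrix(rnorm(S * S, 0, spec@noiseSigma), S, S))
  }

  # cup pallor: the cup looks pale (whitish) against the pink neuroretinal
  # rim.  The shift is chromatic only — luminance is preserved — so
  # grayscale-based localization is unaffected while the pale region's size
  # tracks the CDR
  pallor <- matrix(0, S, S)
  pallor[u2 <= spec@cdr^2 & !dark] <- spec@cupPallor
  img <- valueToImage(V, spec@channelMix, imageId, pallor = pallor)
  retinaCircle <- circleProposal(g$rcx, g$rcy, g$R)
  odCircle <- circleProposal(g$ox, g$oy, max(g$a, g$b))

  if (spec@fringe == "arc") {
    img <- addFringe(img, retinaCircle, extent = spec@fringeExtent,
                     brightness = spec@fringeBrightness, seed = seeds[3],
                     thicknessFrac = spec@fringeThicknessFrac)
  }
  if (spec@nReflections > 0L) {
    img <- addReflections(img, retinaCircle, count = spec@nReflections,
                          seed = seeds[4], avoid = odCircle,
                          sigmaRange = spec@reflectionSigma,
                          peakRange = spec@reflectionPeak)
  }

  gt <- new("GroundTruth",
            odBox = ellipseToBox(g$ox, g$oy, g$a, g$b, S, S),
            odCircle = odCircle,
            label = if (spec@cdr > labelThreshold) "glaucoma" else "healthy",
            cdr = spec@cdr, labelThreshold = labelThreshold)
  list(image = img, gt = gt)
}

#' Add a bright fringe arc at the retinal rim
#'
#' Emulates ambient light leaking past the eye cup: pixels inside a thin
#' annulus arc at the retinal rim are raised toward `brightness` (all three
#' channels, i.e. a whitish glare).  All other pixels are unchanged.
#'
#' @param image a [FundusImage-class].
#' @param retina the retina [CircleProposal-class] (must lie inside the
#'   image).
#' @param extent angular extent of the arc in degrees, `> 0`.
#' @param brightness target intensity the arc is pulled toward.
#' @param seed seed for the arc's (random) angular position.
#' @param thicknessFrac annulus thickness as a fraction of the retina radius.
#' @return A new [FundusImage-class].
#' @export
addFringe <- function(image, retina, extent, brightness, seed = 1,
                      thicknessFrac = 0.025) {
  if (extent <= 0) stop("fringe extent must be > 0 degrees")
  d <- dim(image@pixels)
  S1 <- d[1]; S2 <- d[2]
  x <- matrix(0:(S2 - 1), S1, S2, byrow = TRUE)
  y <- matrix(0:(S1 - 1), S1, S2)
  dx <- x - retina@cx; dy <- y - retina@cy
  rad <- sqrt(dx^2 + dy^2)
  annulus <- rad <= retina@r & rad >= retina@r * (1 - thicknessFrac)
  alpha0 <- withSeed(seed, runif(1, 0, 2 * pi))
  ang <- atan2(dy, dx)
  dAng <- abs(((ang - alpha0 + pi) %% (2 * pi)) - pi)
  sel <- annulus & dAng <= (extent / 2) * pi / 180
  px <- image@pixels
  for (ch in 1:3) {
    plane <- px[, , ch]
    plane[sel] <- roundHalfUp(plane[sel] +
                                0.85 * pmax(0, brightness - plane[sel]))
    px[, , ch] <- plane
  }
  fundusImage(px, image@imageId, image@originalSize)
}

#' Add shiny cloud-like reflection blobs
#'
#' Bright Gaussian blobs emulating light reflected off the ocular fundus
#' (common in younger patients).  Blob centres are sampled inside the retina
#' but kept away from the optic disc when `avoid` is given: each centre is at
#' least `avoid@r + 3 * sigma` from the disc centre.
#'
#' @param image a [FundusImage-class].
#' @param retina the retina [CircleProposal-class].
#' @param count number of blobs; `0` returns the image unchanged.
#' @param seed RNG seed for blob placement and shape.
#' @param avoid optional [CircleProposal-class] (the OD) blobs must not touch.
#' @param sigmaRange,peakRange length-2 ranges for per-blob Gaussian sigma
#'   (pixels) and peak added intensity.
#' @return A new [FundusImage-class].  The attribute `"blobs"` carries a
#'   matrix of the sampled `(cx, cy, sigma, peak)` per blob.
#' @export
addReflections <- function(image, retina, count, seed = 1, avoid = NULL,
                           sigmaRange = c(10, 25), peakRange = c(120, 190)) {
  count <- as.integer(count)
  if (count < 0L) stop("count must be >= 0")
  if (count == 0L) return(image)
  d <- dim(image@pixels)
  blobs <- withSeed(seed, {
    out <- matrix(NA_real_, count, 4,
                  dimnames = list(NULL, c("cx", "cy", "sigma", "peak")))
    for (i in seq_len(count)) {
      for (try in 1:200) {
        sg <- runif(1, sigmaRange[1], sigmaRange[2])
        rr <- sqrt(runif(1)) * 0.8 * retina@r
        th <- runif(1, 0, 2 * pi)
        cx <- retina@cx + rr * cos(th)
        cy <- retina@cy + rr * sin(th)
        ok <- is.null(avoid) ||
          sqrt((cx - avoid@cx)^2 + (cy - avoid@cy)^2) > avoid@r + 3 * sg
        if (ok) break
      }
      if (!ok) stop("could not place reflection blob away from the OD")
      out[i, ] <- c(cx, cy, sg, runif(1, peakRange[1], peakRange[2]))
    }
    out
  })
  x <- matrix(0:(d[2] - 1), d[1], d[2], byrow = TRUE)
  y <- matrix(0:(d[1] - 1), d[1], d[2])
  add <- matrix(0, d[1], d[2])
  for (i in seq_len(count)) {
    add <- add + blobs[i, "peak"] *
      exp(-((x - blobs[i, "cx"])^2 + (y - blobs[i, "cy"])^2) /
            (2 * blobs[i, "sigma"]^2))
  }
  px <- image@pixels
  for (ch in 1:3) {
    px[, , ch] <- as.integer(clamp(roundHalfUp(px[, , ch] + add), 0, 255))
  }
  out <- fundusImage(px, image@imageId, image@originalSize)
  attr(out, "blobs") <- blobs
  out
}

#' Default parameter ranges for random scene sampling
#'
#' The ranges from which [randomSpec()] and [generateDataset()] draw
#' per-image parameters.  They emulate the inter-image variation of real
#' fundus photographs: illumination and contrast levels, disc size around
#' the typical disc-to-retina ratio, disc position nasal of centre, and the
#' clinically distinct CDR ranges of healthy (~0.25-0.55) and glaucomatous
#' (~0.70-0.90) eyes.  `fringeProb`/`reflectionProb` default to 0 (clean
#' scenes).
#'
#' @param ... named overrides of individual ranges.
#' @return Named list of ranges (length-2 numeric) and scalar settings.
#' @export
syntheticRanges <- function(...) {
  ranges <- list(
    imageSize = 1500,
    retinaRadiusFrac = c(0.88, 0.97),
    retinaCenterJitter = 15,
    odEccentricity = c(0.35, 0.6),
    odAngle = c(0, 2 * pi),
    odRadiusFrac = c(0.09, 0.11),
    odAxisRatio = c(0.9, 1.1),
    cdrHealthy = c(0.25, 0.55),
    cdrGlaucoma = c(0.70, 0.90),
    odBrightness = c(150, 185),
    cupDelta = c(45, 70),
    cupPallor = c(18, 32),
    backgroundLevel = c(4, 12),
    retinaLevel = c(70, 105),
    nVessels = c(6, 10),
    vesselDarkness = c(30, 55),
    vesselWidth = c(5, 8),
    noiseSigma = c(3, 6),
    greenMix = c(0.5, 0.62),
    blueMix = c(0.18, 0.3),
    fringeProb = 0,
    fringeExtent = c(40, 160),
    fringeBrightness = c(210, 250),
    fringeThicknessFrac = c(0.015, 0.03),
    reflectionProb = 0,
    maxReflections = 3
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(ranges))
  if (length(bad)) stop("unknown range name(s): ", paste(bad, collapse = ", "))
  if (any(vapply(dots, length, 1L) == 0L)) stop("empty range supplied")
  ranges[names(dots)] <- dots
  ranges
}

#' Draw one random SyntheticSpec from parameter ranges
#'
#' @param ranges a list from [syntheticRanges()].
#' @param label `"healthy"` or `"glaucoma"`: selects the CDR range.
#' @param seed seed controlling both the parameter draw and the rendered
#'   scene.
#' @return A [SyntheticSpec-class].
#' @export
randomSpec <- function(ranges = syntheticRanges(),
                       label = c("healthy", "glaucoma"), seed = 1) {
  label <- match.arg(label)
  u <- function(r) if (length(r) == 2L) runif(1, r[1], r[2]) else r
  withSeed(seed, {
    odB <- u(ranges$odBrightness)
    cdr <- u(if (label == "glaucoma") ranges$cdrGlaucoma else
               ranges$cdrHealthy)
    jit <- ranges$retinaCenterJitter
    fringe <- runif(1) < ranges$fringeProb
    nRefl <- if (runif(1) < ranges$reflectionProb)
      sample.int(ranges$maxReflections, 1) else 0L
    syntheticSpec(
      imageSize = ranges$imageSize,
      retinaRadiusFrac = u(ranges$retinaRadiusFrac),
      retinaCenterJitter = runif(2, -jit, jit),
      odEccentricity = u(ranges$odEccentricity),
      odAngle = u(ranges$odAngle),
      odRadiusFrac = u(ranges$odRadiusFrac),
      odAxisRatio = u(ranges$odAxisRatio),
      cdr = cdr, cupPallor = u(ranges$cupPallor),
      odBrightness = odB,
      cupBrightness = min(255, odB + u(ranges$cupDelta)),
      backgroundLevel = u(ranges$backgroundLevel),
      retinaLevel = u(ranges$retinaLevel),
      nVessels = sample(seq.int(ranges$nVessels[1], ranges$nVessels[2]), 1),
      vesselDarkness = u(ranges$vesselDarkness),
      vesselWidth = u(ranges$vesselWidth),
      fringe = if (fringe) "arc" else "none",
      fringeExtent = u(ranges$fringeExtent),
      fringeBrightness = u(ranges$fringeBrightness),
      fringeThicknessFrac = u(ranges$fringeThicknessFrac),
      nReflections = nRefl,
      noiseSigma = u(ranges$noiseSigma),
      channelMix = c(1, u(ranges$greenMix), u(ranges$blueMix)),
      seed = sample.int(.Machine$integer.max %/% 4L, 1))
  })
}

#' Generate a labelled synthetic dataset with manifest
#'
#' Draws `n` scenes from `ranges` with exactly
#' `round(n * glaucomaFraction)` glaucoma labels (CDR sampled from the
#' class-conditional range, so labels and CDRs are consistent with
#' `labelThreshold`), renders them, and returns a manifest of specs and
#' ground truth.  Fully reproducible under `seed`.
#'
#' @param n number of images, `>= 1`.
#' @param ranges parameter ranges from [syntheticRanges()].
#' @param glaucomaFraction fraction of glaucoma labels in `[0, 1]`; the
#'   default mirrors the roughly one-quarter positive rate of public
#'   glaucoma screening cohorts.
#' @param seed base seed.
#' @param labelThreshold CDR cut-off for the glaucoma label.
#' @param dir if given, images are written there as PNG (with
#'   `manifest.csv` and `specs.json`) and not kept in memory; otherwise all
#'   rendered images are returned (memory: ~`n` x 3 x imageSize^2 x 4 bytes).
#' @return `list(manifest = data.frame, specs = list, items = list or NULL)`;
#'   each item is a `list(image, gt)` as from [generateImage()].
#' @export
generateDataset <- function(n, ranges = syntheticRanges(),
                            glaucomaFraction = 168 / 650, seed = 1,
                            labelThreshold = 0.65, dir = NULL) {
  stopifnot(n >= 1, glaucomaFraction >= 0, glaucomaFraction <= 1)
  nG <- roundHalfUp(n * glaucomaFraction)
  labels <- withSeed(seed, sample(rep(c("glaucoma", "healthy"), c(nG, n - nG))))
  seeds <- deriveSeeds(seed + 1L, n)
  if (!is.null(dir) && !dir.exists(dir)) {
    dir.create(dir, recursive = TRUE)
  }
  keep <- is.null(dir)
  items <- if (keep) vector("list", n) else NULL
  specs <- vector("list", n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    id <- sprintf("syn%04d", i)
    sp <- randomSpec(ranges, labels[i], seed = seeds[i])
    res <- generateImage(sp, imageId = id, labelThreshold = labelThreshold)
    path <- NA_character_
    if (!is.null(dir)) {
      path <- file.path(dir, paste0(id, ".png"))
      writeFundus(res$image, path)
    }
    gt <- res$gt
    rows[[i]] <- data.frame(
      image_id = id, path = path,
      x_min = gt@odBox@xMin, y_min = gt@odBox@yMin,
      x_max = gt@odBox@xMax, y_max = gt@odBox@yMax,
      cx = gt@odCircle@cx, cy = gt@odCircle@cy, r = gt@odCircle@r,
      label = gt@label, cdr = gt@cdr, seed = sp@seed,
      stringsAsFactors = FALSE)
    specs[[i]] <- sp
    if (keep) items[[i]] <- res
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(dir)) {
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE)
    jsonlite::write_json(lapply(specs, specAsList),
                         file.path(dir, "specs.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(manifest = manifest, specs = specs, items = items)
}

# Plain-list view of a spec for JSON emission.
specAsList <- function(spec) {
  nm <- slotNames(spec)
  out <- lapply(nm, function(s) slot(spec, s))
  names(out) <- nm
  out
}
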