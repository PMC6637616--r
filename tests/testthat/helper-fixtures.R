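# Shared fixtures, built once per test run.  Everything is generated in
# code under fixed seeds; nothing is read from disk.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, builder(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# A clean mid-sized scene rendered at 600 px (no artifacts).
smallScene <- function() {
  fixture("smallScene", function() {
    generateImage(syntheticSpec(imageSize = 600, seed = 11))
  })
}

smallConfig <- function() heuristicConfig(workingSize = 600)

# Tiny localization ground truth / prediction stores.
toyAnnotations <- function(n = 5, seed = 3) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(n), function(i) {
    x0 <- sample(0:50, 1); y0 <- sample(0:50, 1)
    annotationRecord(sprintf("img%02d", i),
                     boundingBox(x0, y0, x0 + sample(20:60, 1),
                                 y0 + sample(20:60, 1)),
                     circleProposal(x0 + 10, y0 + 10, 10))
  }))
}

randomBox <- function(limit = 60) {
  x <- sort(sample(0:limit, 2)); y <- sort(sample(0:limit, 2))
  boundingBox(x[1], y[1], x[2] + 1, y[2] + 1)
}

# Pixel-rasterization oracle for box overlap: count pixel centres.
rasterIou <- function(a, b, limit = 80) {
  g <- expand.grid(x = 0:limit, y = 0:limit)
  inA <- g$x >= a@xMin & g$x < a@xMax & g$y >= a@yMin & g$y < a@yMax
  inB <- g$x >= b@xMin & g$x < b@xMax & g$y >= b@yMin & g$y < b@yMax
  sum(inA & inB) / sum(inA | inB)
}

rasterCoverage <- function(pred, gt, limit = 80) {
  g <- expand.grid(x = 0:limit, y = 0:limit)
  inP <- g$x >= pred@xMin & g$x < pred@xMax & g$y >= pred@yMin & g$y < pred@yMax
  inG <- g$x >= gt@xMin & g$x < gt@xMax & g$y >= gt@yMin & g$y < gt@yMax
  sum(inP & inG) / sum(inG)
}

# Brute-force AUC as pair concordance with half credit for ties.
concordanceAuc <- function(scores, labels, positive = "glaucoma") {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  pairs <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(pairs)
}

# A small separable disc set for fast training tests (67-px input network).
tinyDiscSet <- function() {
  fixture("tinyDiscSet", function() {
    cdrBenchmarkDataset(nPerClass = 16, seed = 7, imageSize = 300,
                        outSize = 72)
  })
}

tinyNetSpec <- function() netSpec(convKernels = c(4, 6, 6, 6),
                                  fcWidths = c(16, 16))
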