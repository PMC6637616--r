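---
title: "Optic-disc localization and glaucoma screening: methods and design"
author: "fundusOD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optic-disc localization and glaucoma screening: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Glaucoma damages the optic nerve head and is screened from colour retinal
fundus photographs, where the optic disc (OD) appears as a bright, roughly
round region crossed by dark vessels.  Screening pipelines typically run in
two stages: first locate the disc, then classify the extracted disc region
as healthy or glaucomatous, because the structural cues of the disease —
above all the cup-to-disc ratio (CDR), the relative size of the pale central
cup within the disc — are concentrated there.

fundusOD implements the desk-scale parts of such a pipeline end to end:

* a **rule-based localizer** that turns brightness structure into a disc
  proposal, suitable for bootstrapping bounding-box ground truth
  semi-automatically (machine proposal, human verification/correction);
* an **annotation store** for that workflow, with lossless CSV round-trips
  and Pascal-VOC XML export for training external detectors;
* the **localization evaluation protocol** (intersection-over-union at a
  ladder of thresholds, coverage fraction, and the weak centre-distance
  criterion some earlier work scored against);
* **classification metrics** (precision, recall, F1, specificity, ROC/AUC,
  sensitivity at fixed specificity, k-fold splits);
* a compact **AlexNet-style CNN** with stratified mini-batch training for
  healthy-versus-glaucoma classification of disc crops; and
* a **synthetic fundus generator** that renders scenes with exact ground
  truth, so that every stage is verifiable without downloading any dataset.

## The rule-based localizer

The pipeline (`localizeDisc()`) processes every image at a fixed working
size (default 1500 × 1500; results are mapped back to the original frame
with independent x/y scale factors):

1. **Retina estimation** (`estimateRetina()`): Otsu's threshold on the
   grayscale luminance separates the bright circular retina from the dark
   background; the estimate is the foreground centroid with radius
   `sqrt(area / pi)`.
2. **Rim cropping** (`cropRim()`): a circular mask at 0.95 of the retina
   radius removes the bright fringe that ambient light can leave at the rim.
3. **Adaptive binarization** (`adaptiveBinarize()`): the threshold is the
   mean of the brightest 1% of non-zero pixels; only disc-core-like regions
   survive.
4. **Morphological cleanup** (`cleanMask()`): erosion with a disc of radius
   4 removes reflective speckle, dilation with a disc of radius 10
   reconnects fragments (radii at the working scale).
5. **Proposal** (`proposeOD()`): the largest connected component's centroid
   and area-equivalent radius, enlarged by `proposalScale = 1.5`, become the
   proposed disc circle; its tight square box, clipped to the image, is the
   proposed annotation.

Parameter choices that the method itself does not pin down are exposed in
`heuristicConfig()` and defaulted as follows:

* **Channel**: grayscale Rec. 601 luminance.  Threshold-based localizers in
  the literature variously use the green or red channel; luminance is the
  neutral choice and keeps the pipeline monotone under the generator's
  channel mixing.
* **Crop margin 0.95**: removes rim artifacts up to 5% of the retina radius
  thick while losing almost no disc candidates (the disc sits well inside
  the rim).
* **Structuring radii 4 / 10** at the 1500 scale: the erosion radius is
  chosen above the speckle scale of reflective artifacts and below the disc
  core radius (tens of pixels); the dilation radius bridges vessel-carved
  gaps in the core.
* **`proposalScale` 1.5**: the binarized core is the upper part of the
  disc's brightness profile, roughly two thirds of the disc radius across
  realistic disc sizes, so scaling the measured radius by 1.5 recovers
  approximately the full disc.
* **Fallback**: if nothing survives cleanup, the proposal falls back to the
  centroid of the brightest 1% of pixels with a radius of a tenth of the
  retina radius, and the record is flagged `low` confidence so a human
  reviewer looks at it first.
* An optional sanity bound on the proposal radius (`maxRadiusFrac`) is
  available but disabled by default; with it enabled, oversized proposals
  take the fallback path.

Degenerate inputs are handled explicitly: an all-dark frame raises
`"no retina found"`, a frame with fewer than 100 non-zero pixels raises
`"image too dark"`, and an all-bright frame is treated as all-foreground
(radius `sqrt(H * W / pi)`).

## Evaluation protocol

Boxes are integer, 0-based and half-open; the conversion to Pascal-VOC's
1-based inclusive convention happens only at the XML boundary
(`xmin + 1`, `xmax` unchanged), which keeps the round trip exact.

`evaluateLocalization()` reports accuracy at each IOU threshold using the
*strict* inequality `IOU > t`, the per-image coverage fraction
`area(pred ∩ gt) / area(gt)` (what "more than half of the disc is inside
the prediction" measures), and mean IOU.  Because "average overlap" is
quoted ambiguously in the literature, the report carries both mean IOU and
mean coverage.  The weak centre criterion — centre distance strictly less
than the expected disc diameter, taken as the larger ground-truth box side
— is reported alongside so its permissiveness relative to IOU thresholds
can be quantified.  Ground-truth images without a prediction count as
incorrect at every threshold.

`sensitivityAtSpecificity()` reads the ROC step function without
interpolation (the highest sensitivity among operating points with
specificity at or above the target).  AUC uses trapezoidal integration over
distinct score thresholds, which is identical to pair concordance with half
credit for ties; the test suite asserts that identity to 1e-12 and checks
the overlap measures against a pixel-rasterization oracle to 1e-9.

## The classifier

`netSpec()` describes a four-convolution, three-dense-layer network in the
AlexNet family: conv1 96 @ 11×11 stride 4, conv2 256 @ 5×5 pad 2, conv3
384 @ 3×3 pad 1, conv4 256 @ 3×3 pad 1; max pooling with window 3 and
stride 2 (overlapping) after conv1, conv2 and conv4; local response
normalization (window 5, k = 2, α = 1e-4, β = 0.75) after conv1 and conv2;
dense widths 1024, 1024 with dropout 0.5; softmax over two classes; ReLU
everywhere else.  Kernel counts and dense widths are configurable because
networks of the full width overfit small screening datasets — the scaled
benchmark below uses conv widths 12/16/24/24 and dense widths 64/64.

Training (`trainNetwork()`) uses a constant learning rate of 1e-4 with the
Adam optimizer and softmax cross-entropy.  Inputs are 256×256×3 disc crops
(`extractDisc()`); the network consumes 227×227 patches — the centre crop
at test time, and optionally (`augment = TRUE`) patches drawn from the
deterministic 15-patch set of `augmentDisc()` ({identity, horizontal flip,
vertical flip} × {four corners, centre}; flips are applied after cropping
so the flip algebra is exact).  Augmentation is off by default, as it has
not shown a significant benefit for this task.

**Stratified batching.** `stratifiedBatches()` partitions the majority
class across the epoch (each majority sample appears exactly once) and
tops every batch up with at least `minMinority` minority samples,
oversampling the minority as needed, so no batch is empty of the rare
class.  One consequence worth knowing: the batch class ratio follows
`(batchSize - minMinority) : minMinority`, not the dataset ratio.  On a
*balanced* dataset a small floor therefore skews batches toward the
"majority" and the network simply learns the batch prior; the balanced
benchmarks set `minMinority = batchSize / 2` so batches stay balanced.

Forward and backward passes for convolution (im2col + BLAS), overlapping
max-pooling and LRN are implemented in compiled code; weight
initialization, dropout masks, batching and Adam run in R under a single
seed, so a training run is exactly reproducible in single-threaded use.
Gradients are verified against finite differences in the test suite.

Cross-validation (`crossValidate()`) uses class-stratified folds (a plain
random 10-way split of an imbalanced cohort can lose the minority class
from a small training partition); fold sizes differ by at most one and the
per-fold reports are aggregated as mean ± sample standard deviation.
Undefined metrics raise errors by default; the cross-validation path uses
`strict = FALSE`, which records `NA` precision for a class a weak fold
model never predicts rather than aborting the whole experiment.

## The synthetic generator

`generateImage()` renders a fundus-like scene from a fully parametric
`SyntheticSpec`: a bright retina disc on a dark background, an elliptical
OD (axis ratio drawn in [0.9, 1.1], so a perfectly circular shortcut is
not available), dark quadratic-Bézier vessel strips radiating from the
disc toward the rim (widths 1–8 px at the 1500 scale, tapering distally),
additive Gaussian noise, and a red-dominant channel mix (R > G > B).
Artifacts are opt-in: a bright fringe arc at the retinal rim
(`addFringe()`, emulating ambient-light leakage) and bright cloud-like
reflection blobs (`addReflections()`, placed at least `3σ + disc radius`
away from the disc).  Identical specs, including the seed, render
bit-identical images; the exact disc ellipse, its tight box, the CDR and
the class label (glaucoma iff CDR > 0.65, between the 0.5 clinical
screening cut-off and severe disease) form the ground truth.

Two rendering choices deserve explanation because they were genuinely
open:

* **Disc brightness profile.** The disc is a *strictly monotone* quadratic
  ramp from `odBrightness` at the margin to `cupBrightness` at the centre,
  with a step ring at the cup boundary.  A flat cup plateau — the obvious
  alternative — breaks mean-of-top-percentile thresholding: when the
  threshold lands inside a flat region, the mask degenerates into
  salt-and-pepper noise that erosion erases.  The monotone ramp guarantees
  a solid, sharp-edged core at any threshold level, which is exactly the
  structure real discs offer a brightness-based localizer.
* **Cup pallor as a chromatic cue.** The cup is whitened (green and blue
  raised, red lowered) with the shift balanced so Rec. 601 luminance is
  unchanged.  This mirrors the clinical appearance — pallor filling the
  cup against the pink neuroretinal rim — and cleanly separates the two
  consumers of the image: the luminance-thresholding localizer is provably
  blind to the pallor, while the classifier receives a colour region whose
  size tracks the CDR.

Default parameter ranges (`syntheticRanges()`) emulate inter-image
variation in illumination, contrast and geometry: retina radius 0.88–0.97
of the half-width with ±15 px centre jitter; disc radius 0.09–0.11 of the
retina radius (a disc-to-retina diameter ratio around 0.2, the typical
clinical value — and the regime a top-1% brightness threshold implicitly
assumes, since the disc then covers roughly 1% of the retina); disc
eccentricity 0.35–0.6 of the maximal offset; CDR 0.25–0.55 for healthy and
0.70–0.90 for glaucomatous eyes (clinically distinct ranges on either side
of the 0.65 label threshold); intensity levels
background < retina < disc ≤ cup with disc 150–185, cup 45–70 above the
disc, noise σ 3–6.  `generateDataset()` draws scenes from these ranges
with an exact class count (`round(n × glaucomaFraction)`; the default
fraction ≈ 0.26 mirrors the imbalance of public screening cohorts) and
emits a manifest (CSV) plus full specs (JSON).

**What the generator does not emulate** — and hence what passing the
synthetic suites does and does not show: real vasculature topology,
peripapillary atrophy, retinopathy lesions, resolution-dependent optics and
sensor artifacts, or the correlation structure of real illumination fields.
The suites demonstrate that the algorithms are implemented correctly and
behave as designed on images with the structural properties they exploit;
they do not certify accuracy on any real dataset.

## Benchmarks and problem sizes

The standard verification suites (used identically by the test suite and
by `scripts/acceptance.R`) are:

* **Localization** (`odLocalizationBenchmark`): 200 clean scenes at
  1500 × 1500 (the native working size), default configuration.  Quality
  floors: accuracy ≥ 95% at IOU > 0.5 and ≥ 99% at IOU > 0.2, with
  accuracy monotone over the threshold ladder 0.2/0.5/0.6/0.7/0.8.
* **Fringe robustness** (`fringeRobustnessBenchmark`): 100 pairs of
  identical scenes with and without a fringe arc (thickness ≤ 3% of the
  retina radius), rendered at 750 px with a 750 px working size — the
  property is scale-free and this keeps the suite fast.  Floor: ≥ 90% of
  pairs shift the predicted centre by ≤ 2% of the image width.
* **Classifier learning** (`cnnLearningBenchmark`): 200 discs at two
  well-separated CDRs (0.3 vs 0.85), scenes rendered at 600 px (the disc
  is still tens of pixels across before the 256 resize), a stratified
  50/50 train/test split, the reduced-width network, 15 epochs, batch 16
  with `minMinority` 8.  Floor: held-out accuracy ≥ 90%.

## Known limitations

* The localizer's default parameters assume the disc is the brightest
  coherent region and that its area is within a factor of ~2 of 1% of the
  retina; very small or very large discs degrade the proposal radius (the
  `proposalScale` constant no longer matches the captured core).
* The CNN trains on CPU in R; it is sized for benchmarks of hundreds of
  images, not for full-scale screening training runs.
* The centre-distance criterion's exact convention in the earlier
  literature is not recoverable; the implementation uses the larger
  ground-truth box side as the "expected diameter", with strict
  inequality.
* Reported IOU thresholds use strict `>`; at floating point this is
  indistinguishable from `>=` except on constructed boundary cases, but it
  is fixed for determinism.
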