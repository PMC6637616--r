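# fundusOD

Optic-disc localization and glaucoma screening for colour retinal fundus
images, in R.

Glaucoma screening from fundus photographs runs in two stages: find the
optic disc (OD), then classify the extracted disc region as healthy or
glaucomatous, because the key structural cue — the cup-to-disc ratio
(CDR), the relative diameter of the pale central cup within the disc — is
concentrated there.  Public fundus datasets typically ship without
bounding-box ground truth for the disc, so the first practical step is a
*semi-automated* annotation workflow: a rule-based algorithm proposes a
disc location for every image, and a human verifies or corrects it.

fundusOD provides that whole desk-scale toolchain:

* **Rule-based localizer** (`localizeDisc()`): at a fixed 1500-px working
  scale, estimate the retina by Otsu thresholding, crop the bright rim
  fringe, binarize at the mean of the top 1% brightest pixels, clean the
  mask with disc-shaped erosion/dilation, and propose a circle (and tight
  box) from the largest blob, scaled by 1.5 since the binarized core is
  the disc's bright centre.  Failures fall back to a brightest-pixel
  centroid flagged `low` confidence for human review.
* **Annotation store** (`saveAnnotations()`, `mergeCorrections()`,
  `exportVocXml()`): machine proposals, human corrections and their merge
  into verified ground truth, with lossless CSV round-trips and
  Pascal-VOC XML export (0-based half-open boxes internally; the ±1
  conversion happens only at the XML boundary).
* **Localization evaluation** (`iou()`, `coverageFraction()`,
  `centerCriterion()`, `evaluateLocalization()`): accuracy at a ladder of
  IOU thresholds (strict `>`), mean IOU and mean GT-coverage, plus the
  permissive centre-distance criterion for comparison.
* **Classification metrics** (`classificationReport()`, `rocAuc()`,
  `sensitivityAtSpecificity()`, `kfoldSplit()`): per-class and
  support-weighted precision/recall/F1 with

  `precision = TP/(TP+FP)`, `recall = TP/(TP+FN)`,
  `F1 = 2·P·R/(P+R)`, `specificity = TN/(TN+FP)`,

  trapezoidal ROC/AUC (equal to pair concordance with tied-pair half
  credit), and k-fold split generation.
* **CNN classifier** (`netSpec()`, `trainNetwork()`, `predictNet()`,
  `crossValidate()`): a four-conv/three-dense AlexNet-style network
  (96@11×11/4 → 256@5×5 → 384@3×3 → 256@3×3, overlapping 3/2 max-pooling,
  local response normalization, dropout 0.5, softmax), trained with Adam
  at a constant 1e-4 on 227×227 patches of 256×256 disc crops, with
  stratified mini-batches that always contain minority-class samples and
  an optional deterministic 15-patch augmentation (flips × five crops).
  Convolution, pooling and LRN kernels are compiled (Rcpp/Armadillo);
  training is exactly reproducible under a seed.
* **Synthetic fundus generator** (`syntheticSpec()`, `generateImage()`,
  `generateDataset()`, `addFringe()`, `addReflections()`): seedable
  scenes — bright retina, elliptical disc with a monotone brightness ramp
  and a chromatically pale cup, radiating vessels, rim-fringe and
  reflection artifacts — with exact box/circle/label/CDR ground truth, so
  every stage above is verifiable without downloading a dataset.

## Worked example

Render a glaucomatous scene, localize the disc, and score the prediction:

```r
library(fundusOD)

sp  <- syntheticSpec(imageSize = 600, cdr = 0.78, seed = 42)
res <- generateImage(sp)
res$gt@odBox
#> BoundingBox [394, 457) x [269, 331)  (63 x 62 px)
res$gt@label
#> [1] "glaucoma"

loc <- localizeDisc(res$image, heuristicConfig(workingSize = 600))
loc
#> ODLocalization 'syn-seed42': centre (426.7, 299.8) r 32.1, normal confidence
iou(loc$box, res$gt@odBox)
#> [1] 0.924
coverageFraction(loc$box, res$gt@odBox)
#> [1] 0.984
```

The predicted box overlaps the true disc box with IOU 0.92 and contains
98% of the true disc area; under the usual correctness rule (IOU > 0.5)
this localization is correct with a wide margin.

Classification metrics work from plain label/prediction vectors.  For a
screening outcome with 412 healthy images (391 called healthy) and 139
glaucomatous images (48 called glaucoma):

```r
labels <- rep(c("healthy", "glaucoma"), c(412, 139))
preds  <- c(rep("healthy", 391), rep("glaucoma", 21),
            rep("glaucoma", 48), rep("healthy", 91))
classificationReport(labels, preds)
#> ClassificationReport
#>      class precision recall     f1 support
#> 1  healthy     81.12  94.90 0.8747     412
#> 2 glaucoma     69.57  34.53 0.4615     139
#> Total: precision 78.21%, accuracy 79.67%, F1 0.7705 (n = 551)
```

The total row is support-weighted; the overall accuracy (79.67%) sits next
to a glaucoma recall of only 34.5% — the reason imbalanced screening
results should never be summarized by accuracy or AUC alone.

A shell front end mirrors the workflows
(`inst/scripts/fundlocate`): `generate`, `localize`, `merge`, `eval-loc`,
`export-voc`, `extract-discs`, `train`, `crossval`, `eval-clf`.

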