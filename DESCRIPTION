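Package: fundusOD
Title: Optic Disc Localization and Glaucoma Screening in Retinal Fundus Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for locating the optic disc in colour retinal fundus
    images and screening the extracted disc for glaucoma. Implements a
    rule-based localizer (Otsu retina estimation, rim cropping, top-1
    percent adaptive binarization and morphological cleanup) used to
    bootstrap bounding-box ground truth semi-automatically, an annotation
    store with human-correction merging and Pascal-VOC export, an
    intersection-over-union evaluation protocol for localization, a full
    set of classification metrics (precision, recall, F1, specificity,
    ROC/AUC, sensitivity at fixed specificity, k-fold splits), a compact
    AlexNet-style convolutional network with stratified mini-batch
    training for healthy-versus-glaucoma classification of disc crops,
    and a seedable synthetic fundus-image generator that provides exact
    ground truth for end-to-end verification of every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    png,
    xml2,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
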