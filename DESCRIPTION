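Package: ivdquant
Title: Quantification and Detection of Narrowed Intervertebral Disc Spaces
    in Lateral Spine Radiograph Segmentations
Version: 0.1.0
Authors@R:
    person("Open", "Imaging", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for screening canine intervertebral disc disease from
    vertebral-body segmentation masks of lateral caudal thoracic and lumbar
    radiographs. Implements a geometric preprocessing pipeline (nearest-neighbour
    resize to 1024x512, morphological skeletonization of vertebral bodies,
    4th-order polynomial centerline fit, a length-1024 binary spine profile and
    pixel-counted inter-vertebral gap widths), a large-kernel one-dimensional
    convolutional network trained with a combined cross-entropy and focal loss
    that labels each centerline position as no disc space, normal disc space or
    narrowed disc space, a synthetic spine-phantom generator with known ground
    truth for validation, and the associated agreement statistics (Cohen's and
    Fleiss' kappa, sensitivity/specificity/PPV/NPV, ROC/AUC with Youden-index
    thresholding).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
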