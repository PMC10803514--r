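Package: mfdnet
Title: Multistage Feature-Distillation Networks for Multi-Label
    Immunomarker Classification of Breast Ultrasound Nodules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Implements a lightweight multistage feature-distillation
    convolutional network (MFD-Net) that classifies breast-ultrasound
    nodule images into four binary immunohistochemical indices (ER, PR,
    HER-2, Ki-67) simultaneously.  Provides the bespoke layer types
    (multi-kernel depthwise convolution, blueprint-separable convolution
    with a low-rank pointwise factorisation, and a serial
    spatial-plus-channel attention gate), a concurrent soft-max objective
    that uses training-set label co-occurrence statistics, plain-SGD
    training with hand-derived gradients, per-index confusion-matrix
    metrics, YOLO-format region-of-interest cropping, the stated
    augmentation families, and a seeded speckle-phantom generator whose
    latent nodule attributes drive the four labels so the whole pipeline
    is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jpeg,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
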