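Package: sfanet
Title: Scale and Feature Aggregating Network for Retinal Vessel Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An encoder-decoder convolutional network for pixel-level retinal
    vessel segmentation in fundus photographs, built around three feature
    aggregation blocks: a residual atrous (dilated) multiscale block at the
    bottleneck, an attentional skip-connection fusion block joining shallow
    encoder features taken before and after subsampling with upsampled decoder
    features, and a multi-path fusion head that gates the finest decoder output
    with coarser decoder stages. Includes a self-contained reverse-mode
    automatic-differentiation engine over dense arrays, a procedural generator
    of fundus-like images with pixel-exact vessel ground truth, patch-based
    training with Adam, overlap-tiled whole-image inference, and pixel-level
    sensitivity/specificity/accuracy/ROC-AUC evaluation restricted to the
    field of view.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    png,
    tiff,
    jsonlite,
    yaml,
    withr,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    EBImage
Config/testthat/edition: 3
RoxygenNote: 7.3.3
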