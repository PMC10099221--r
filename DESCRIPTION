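Package: grainseg
Title: Instance Segmentation of Densely Packed Wheat Kernels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Detection and pixel-level segmentation of unsound wheat kernels
    (moldy, injured, spotted, sprouted, broken) in images of densely packed,
    partially adherent grain. Provides a seeded synthetic scene generator with
    visible-region instance masks and COCO/labelme interchange, channel
    attention blocks (ECA, SE, CBAM), top-down and bottom-up feature pyramid
    fusion, a region-proposal stage with configurable anchor design and
    non-maximum suppression, a compact CPU-trainable Mask-RCNN-style detector,
    and COCO-style evaluation metrics (precision, recall, AP, mAP, AR, mIoU).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    grDevices,
    jsonlite,
    png,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
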