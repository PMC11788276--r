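Package: serpensgate
Title: Snake-Convolution and Super-Token Detection Networks for Plant
    Disease Imagery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Building blocks and a full single-stage detector for plant
    disease imagery: dynamic snake (serpentine deformable) convolution,
    super-token attention with soft k-means token clustering, spatial
    pyramid pooling with efficient layer aggregation (SPPELAN), a
    declarative 24-row model graph with an exact per-layer parameter
    audit, YOLO-format dataset input/output with mosaic and letterbox
    augmentation, detection metrics (precision, recall, F1, per-class
    average precision, mAP@0.5, confusion matrices), a deterministic
    synthetic leaf-lesion scene generator, and desk-scale CPU training
    with a Wise-IoU box loss and gradient-based class activation maps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    png,
    yaml,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
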