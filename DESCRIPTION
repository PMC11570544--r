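Package: cmtt
Title: Test-Time Adaptive Cell Segmentation and Joint Detection-Embedding Tracking
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Two-stage fully test-time adaptation (CMTT) for microscopy cell
    segmentation, combining entire-image Shannon-entropy and batch nuclear-norm
    minimization with patch-level central-metric contrastive adaptation, all
    restricted to batch-normalization parameters of a compact encoder-decoder
    segmentation network. On top of the adapted feature pyramid, a joint
    detection and re-identification head (focal + CIOU detection losses, a
    spatial-attention ReID branch) feeds an online JDE-style tracker producing
    Cell Tracking Challenge style lineage tables. Includes a synthetic cell
    video generator with controllable photometric domain shift and density,
    CTC-layout TIFF input/output, and the full segmentation and tracking metric
    suite (Dice, IOU, AJI, MOTA, CT, TF, MT, ML, cell imaging density).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    tiff,
    EBImage,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
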