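Package: rppgtwin
Title: Camera-Based Vital-Sign Fusion via Remote Photoplethysmography
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A machine-learning digital-twin pipeline that estimates heart
    rate, breathing rate and blood-oxygen saturation from facial video using
    remote photoplethysmography (rPPG). Provides a video-to-time-series
    extraction front end (face detection, 68-point landmarks, three facial
    regions of interest, green-channel averaging, 150-sample non-overlapping
    buffers), a synthetic rPPG clip and trace generator with known ground
    truth, subject-disjoint data engineering, three regression model
    families (gradient-boosted trees, multilayer perceptron, LSTM),
    formula-defined evaluation metrics, and a runtime loop that emits fused
    vital-sign readings every 30 frames.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    grDevices,
    jsonlite,
    Rcpp,
    stats,
    tibble,
    tools,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
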