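Package: uavcolor
Title: In-Flight Color Correction of UAV Crop Imagery with a Reference Chart
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Radiometric color calibration of aerial RGB imagery for plant
    phenotyping. Detects a 24-patch ColorChecker reference chart in every
    frame by keypoint matching and homography estimation, fits a
    bias-augmented linear color correction matrix per frame by least
    squares, applies it to the imagery, and quantifies color accuracy with
    the CIEDE2000 color difference. Includes cross-sensor consistency
    metrics, exposure-normalized brightness, chart-occlusion mask
    generation for mosaicking, plot-level color summaries, and a fully
    ground-truthed synthetic scene generator so the complete pipeline is
    verifiable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    farver,
    tiff,
    jpeg,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
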