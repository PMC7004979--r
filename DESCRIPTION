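Package: amst
Title: Alignment of FIB-SEM Image Stacks to a Median-Smoothed Template
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Fine alignment of serial-section electron microscopy image
    stacks. Each raw slice is registered with an affine transform, by
    mutual-information maximisation, to a morphology-preserving template
    obtained by z-axis median filtering of a translation-only
    pre-alignment (fiducial template matching or slice-to-slice phase
    correlation). Includes the displacement-error evaluation scheme used
    to quantify alignment quality in nanometers, lossless TIFF stack
    input/output, and a seeded synthetic phantom generator with known
    per-slice ground-truth distortions for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tiff,
    png,
    jsonlite,
    stats,
    grDevices,
    graphics,
    utils,
    parallel
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
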