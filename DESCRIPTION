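Package: periapex
Title: Peri-Implantitis Damage Assessment on Periapical Radiographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-stage analysis of dental periapical radiographs for
    peri-implantitis assessment. A grid-based single-class convolutional
    detector locates implant-thread regions, each detection is cropped and
    split into mesial/distal half-images along a regression-fitted midline,
    the halves are enhanced with a histogram-equalization, gradient and
    region-coloring chain, and an AlexNet-style convolutional classifier
    labels each half as damaged or healthy. Includes a synthetic-radiograph
    generator with ground truth, confusion-matrix evaluation in the
    percent-of-total table convention, and an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    utils,
    yaml,
    EBImage
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
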