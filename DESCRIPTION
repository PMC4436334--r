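Package: eggCounter
Title: Density-Estimation Counting of Drosophila Eggs in Vial Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Supervised counting of Drosophila eggs (and similar small
    bright objects) in photographs of vial food surfaces, without explicit
    detection or segmentation. Sparse dot annotations are converted into
    Gaussian density maps, per-pixel multiscale filter features (Gaussian
    gradient magnitude, Laplacian of Gaussian, structure tensor
    eigenvalues at five scales on three colour channels) are regressed
    onto density with an ensemble of extremely randomized trees, and
    region counts are obtained by summing the predicted density. A linear
    bias correction fitted by least squares on training-region counts
    removes the systematic over-estimation of sparse vials and
    under-estimation of dense ones, with 95% prediction intervals on
    corrected counts. Includes the percent-accuracy metric, a
    leave-one-out cross-validation protocol with statistical replicates,
    batch evaluation to CSV, a seeded synthetic vial-image generator for
    testing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    ranger,
    EBImage,
    png,
    tiff,
    jsonlite,
    optparse
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
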