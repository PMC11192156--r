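Package: seedmorph
Title: Morphometric Seed Identification from Flatbed Scans
Version: 0.1.0
Authors@R:
    person("Seed", "Morphometrics", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An automated pipeline for counting and identifying tree seeds
    collected in forest seed traps. Binary flatbed-scanner images are
    segmented into individual seed particles, a full suite of ImageJ-style
    shape and intensity descriptors (area, perimeter, fitted-ellipse axes,
    Feret diameters by rotating calipers, circularity, solidity, and more)
    is measured in calibrated units, and seeds are classified to species
    with a random forest grown on Gini splits with out-of-bag error and
    mean-decrease-in-Gini importance. Includes exact binomial confidence
    intervals, Cohen's kappa and confusion-matrix reporting, reconciliation
    of duplicate scans into consensus counts with a discrepancy measure,
    and a synthetic-scan generator of winged conifer-like seed silhouettes
    for fully reproducible end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    grDevices,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
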