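Package: wormspan
Title: Longevity Biomarkers for Individually Cultured Nematodes from
    Longitudinal Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: End-to-end analysis of individually reared Caenorhabditis
    elegans observed by daily brightfield and fluorescence microscopy:
    segmentation of the animal with a distance-transform least-cost
    centerline, straightening and warping to an age-specific "unit worm",
    phenotypic biomarkers (size, corrected fluorescence percentiles,
    motion and texton-based texture scores mapped to remaining lifespan by
    nu-SVR), eigen-image analysis of reporter expression patterns,
    day-window summaries with ordinary least-squares and leave-one-out
    cross-validated lifespan prediction, a standardized-weight survival
    prediction index, partial-correlation biomarker networks via the PC
    skeleton search, and time-resolved ridge regression with
    generalized-cross-validation penalty selection.  A seeded synthetic
    cohort and worm-image generator with pixel-level ground truth makes
    every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    igraph,
    EBImage,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    tiff,
    png
Config/testthat/edition: 3
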