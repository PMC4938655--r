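Package: larvatrack
Title: Single-Larva Crawl Tracking and Thermogenetic Screen Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying Drosophila larval crawling behavior from
    low-magnification time-lapse recordings and for calling hits in
    thermogenetic activation screens. Implements per-frame single-animal
    segmentation (Gaussian blur, Otsu threshold, morphological closing,
    size-gated object selection), centroid-based instantaneous speed and
    body-length estimation with a half-body-length displacement exclusion
    rule, paired permissive/restrictive temperature normalization, and
    two-criterion one-tailed Welch-test classification of slow genotypes.
    Includes a ground-truthed synthetic crawl-video and screen-data
    simulator so every stage of the pipeline can be validated against
    known kinematics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
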