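Package: molseg
Title: Noise-Free Extraction of Molecular Structure Depictions from Document Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A three-stage pipeline for retrieving clean molecular-structure
    depictions from scientific-document page images: detect candidate structure
    regions and crop them with an expanded bounding box, generate a two-valued
    mask map ({0, 128}) per crop through a pluggable segmenter, then denoise and
    separate the masks by connected-component labeling and the pixel-ratio (PR)
    statistic with a configurable threshold, emitting one clean image per
    structure. Includes pluggable detector and segmenter backends with
    rule-based baselines, a seeded synthetic page/mask fixture generator with
    exact ground truth, and an end-to-end orchestrator with recovery metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    purrr,
    tibble,
    rlang,
    jsonlite,
    yaml,
    png,
    EBImage,
    Rcpp,
    ggplot2,
    grDevices,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
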