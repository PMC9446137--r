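Package: woundlabel
Title: Headless Superpixel-Assisted Labeling of Wound Tissue Photographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Scriptable, headless tooling for semantic labeling of chronic
    wound photographs into tissue classes (intact skin, granulation, slough,
    necrotic, background). Generates segmentation proposals with efficient
    graph-based segmentation (Felzenszwalb), SLIC and Quickshift superpixels,
    and k-means intensity clustering; composes selected segments, brush
    strokes and tolerance-based flood fills into per-pixel label masks;
    replays deterministic session scripts; evaluates label maps against a
    reference with per-class precision, recall and F-score; and ships a
    seeded synthetic wound-scene generator with ground truth for end-to-end
    testing without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    png,
    jpeg,
    withr,
    tibble
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
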