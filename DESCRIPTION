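Package: ancmorph
Title: Morphometry of the Cephalopod Axial Nerve Cord
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantitative morphometry for segmentation analysis of the
    cephalopod axial nerve cord (ANC). Reads and validates SWC neurite
    reconstructions, computes three-dimensional Sholl branching profiles
    with polynomial fits, nerve exit trajectory vectors, circular
    angular-coverage ("suckerotopy") statistics on labelled nerve tips,
    segment- and sucker-level measurements with a factorial ANOVA and
    Tukey post-hoc stage, and nuclei counting on grayscale image patches
    by thresholding and connected-component analysis. A synthetic-data
    module generates rooted branching trees, labelled tip sets,
    morphometric tables and blob images with machine-readable ground
    truth so every pipeline stage is testable without microscopy data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    car,
    igraph,
    png,
    tiff
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
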