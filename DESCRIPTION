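Package: ltfscore
Title: Simulation and Scoring for Ex Vivo Live Tumor Fragment Cytokine Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the computational core of ex vivo live tumor fragment
    (LTF) immunotherapy-response assays. Simulates tissue fragmentation and
    randomized pooling on marker-labeled 2D cell maps to quantify how fragment
    geometry and pool size suppress tumor-heterogeneity sampling noise;
    handles multiplex cytokine measurement tables with limit-of-quantitation
    censoring and replicate quality control; scores cross-well checkpoint
    inhibitor response with MAD-trimmed modified Z-scores, Ward clustering and
    biomarker enrichment tests; and scores sequential same-well treatment via
    per-phase secretion-rate slopes and their fold change. Includes a
    synthetic cohort generator with known ground truth for end-to-end
    validation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
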