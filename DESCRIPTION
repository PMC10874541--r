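Package: pexscreen
Title: High-Content Screening Analysis of Peroxisomal Abundance with
    Cell-Cycle Deconfounding
Version: 0.1.0
Authors@R:
    person("HCS", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for high-content imaging screens of
    peroxisomal abundance in adherent cell lines carrying a fluorescent
    peroxisome reporter and a DNA counterstain. Provides nuclear
    segmentation with edge and cluster exclusion, neighbour-constrained
    simulated-cytoplasm compartmentalization, punctate spot detection and
    per-cell intensity integration, DNA-content cell-cycle gating (2N/4N),
    percent-of-control standardization with percentile-based compound
    categorization, and flow-cytometry-style event analyses (viability
    gating, ROS fold-change, condition comparisons). A ground-truthed
    synthetic-data generator emulates the screen design so every stage is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    graphics,
    grDevices,
    jsonlite,
    Rcpp,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
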