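Package: mstfc
Title: Minimum Spanning Tree Analysis of Resting-State Functional Connectivity
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for studying predisposing delirium risk
    factors through resting-state fMRI functional networks. Provides temporal
    denoising of region-of-interest BOLD time series (initial-volume deletion,
    framewise-displacement scrubbing, 36-parameter nuisance regression,
    band-pass filtering, duration and motion gates), Pearson functional
    connectivity matrices over the Power 264-region parcellation, maximum-weight
    spanning-tree backbones via Kruskal's algorithm with global strength,
    diameter and leaf-fraction metrics, regional PCC-DLPFC connectivity, and
    group-level linear models with standardized coefficients and
    Benjamini-Hochberg false-discovery-rate correction. A seeded synthetic
    cohort generator with planted covariate effects makes every stage testable
    without access to scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
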