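Package: miniconn
Title: Functional Microcircuit Networks from Calcium Imaging with Nested
    Cross-Validated Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds binarized functional-connectivity graphs from
    single-neuron calcium (dF/F) traces recorded across behavioral stages,
    quantifies their topology (characteristic path length, local and global
    clustering, degree-tail hub statistics) and cross-stage reconfiguration
    via the Laplacian spectral distance, and feeds the resulting
    session-level indices into genotype-balanced nested leave-pairs-out
    random-forest models with recursive feature elimination, feature
    selection frequencies and in-silico feature ablation. Includes a
    synthetic-cohort generator that simulates stage-structured calcium
    traces from ground-truth small-world networks so every stage of the
    pipeline can be validated against known structure.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr,
    ranger,
    pROC
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
RoxygenNote: 7.3.3
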