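Package: tnmca
Title: Drug Indication Inference by Typed Network Motif Comparison
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers new drug-disease indication edges in heterogeneous
    biomedical interaction networks (chemicals, genes, diseases, pathways)
    by typed network motif comparison analysis (TNMCA). Enumerates connected
    k-node induced subgraphs, groups them into typed network motifs via
    canonical labeling of vertex- and edge-labeled multigraphs, proposes
    candidate indications by single-edge motif completion, aggregates
    evidence with a normalized noisy-OR score, and evaluates ranked
    candidates against a held-out answer set with tie-aware ROC/AUC,
    including Swanson-style ABC transitive inference as a baseline.
    Ships a seeded synthetic-network generator with planted motif
    instances so the whole pipeline is testable without database access.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
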