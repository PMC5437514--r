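Package: netfingerprint
Title: Knowledge-Based Network Fingerprints for Gene Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Characterizes a query gene network as a vector of
    permutation-normalized similarity scores (a "network fingerprint")
    against an ordered set of reference pathway networks.  Node-node
    mapping between two networks is found by affinity propagation
    clustering on a merged graph (or a greedy aligner, or an external
    alignment tool), edge weights come from Gene Ontology semantic
    similarity (Lin measure with best-match averaging) or a precomputed
    gene-gene similarity matrix, and raw network similarity scores are
    normalized to Z-scores against a topology-preserving label-permutation
    null.  Includes hypergeometric over-representation analysis with
    Benjamini-Hochberg correction, an enrichment-based ROC/AUC validation
    harness, a synthetic-universe generator for planted-module benchmarks,
    and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
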