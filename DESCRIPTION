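Package: coexrank
Title: Co-Expression Network Inference, Network-Based Gene Re-Ranking and
    Conserved Pattern Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for multi-cohort gene co-expression analysis: statistical
    network inference over differentially expressed genes (ARACNE, CLR,
    MRNET, MRNETB, C3NET, Spearman adjacency, shrinkage partial correlation,
    neighbourhood lasso and tree-ensemble importance), network-based gene
    re-ranking by a PageRank-style reconciliation of differential-expression
    scores with network topology, scoring of ranked gene lists by hold-out
    SVM classification with sequential gene inclusion, extraction of the
    conserved network pattern shared across cohorts by edge intersection and
    dynamic weakest-edge filtering, and drug-repurposing table summaries
    (unique/exclusive/shared drug counts, exact hypergeometric overlap
    probabilities, Tanimoto fingerprint clustering and typed super-network
    assembly). A synthetic multi-cohort generator with planted differential
    expression and a planted conserved co-expression module makes every
    stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    e1071,
    glmnet,
    ranger,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
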