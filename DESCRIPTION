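Package: po2go
Title: Partial-Order Contrastive Gene Ontology Term Embeddings and Joint
    Protein Function Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns Gene Ontology (GO) term embeddings with a contrastive
    objective driven by shortest-reachable-path (SRP) partial-order
    constraints over the is_a/part_of DAG (PO2Vec), and couples them with
    fixed protein feature vectors in a joint projection predictor for
    multi-label protein function prediction (PO2GO). Includes an OBO/GAF
    reader, stratified positive/negative sampling with a balanced InfoNCE
    loss, embedding-quality evaluations (depth probing, ancestor
    distinguishability via the 1-Wasserstein distance, domain silhouette,
    best-match-average semantic similarity correlations), the CAFA-style
    function-prediction metric suite (Fmax, Smin, micro-AUPR, information
    content, few-shot binned F1), and seeded synthetic generators for
    multi-domain DAGs, true-path-consistent annotations and signal-bearing
    protein vectors so the whole stack runs end-to-end offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils,
    tibble,
    dplyr,
    ggplot2,
    rlang,
    withr,
    cluster,
    nnet,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
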