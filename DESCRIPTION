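Package: strucsynergy
Title: Drug Combination Synergy Prediction from Structural Network Embeddings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts whether a drug pair acts synergistically or
    antagonistically in a given cancer cell line using only the topology of a
    protein-protein interaction (PPI) network. Protein nodes are embedded by a
    structural-identity method: per-hop degree-ring fingerprints compared with
    dynamic time warping, a multilayer similarity graph, biased random walks,
    and Skip-Gram training with negative sampling. Drug and cell-line feature
    vectors are mean-pooled over their target proteins, concatenated per
    drug-drug-cell-line triple, and classified with gradient-boosted trees
    under repeated stratified cross-validation. Includes a synthetic study
    generator with planted structural roles for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils,
    xgboost
LinkingTo:
    Rcpp
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
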