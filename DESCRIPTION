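Package: ddimamba
Title: Cross-Modal Selective State-Space Fusion for Drug-Drug Interaction
    Type Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies drug-drug interaction (DDI) sentences into the five
    DDIExtraction2013 relation types (Advice, Mechanism, Effect, Int,
    Negative) from multimodal drug-pair input: the mention sentence, each
    drug's description text, its SMILES string and its molecular graph.
    Per-drug channel embeddings are concatenated, reduced by PCA, encoded by
    a selective state-space (Mamba) block, and fused across the pair by a
    partial cross-attention layer followed by a second Mamba block with a
    residual connection; a convolutional refinement and pooled join feed a
    sigmoid classification head. Training handles class imbalance with SMOTE
    oversampling and inverse-frequency class weights. Includes macro
    precision/recall/F1 and rank-AUC evaluation with stratified k-fold
    cross-validation, a seeded synthetic-corpus generator with a planted
    class signal for end-to-end testing, and import/export of a JSONL
    drug-pair interchange format.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    igraph,
    ChemmineR,
    ChemmineOB,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
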