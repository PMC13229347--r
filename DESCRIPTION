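Package: quadnet
Title: Quad-Stream Attention Networks for Protein-Protein Interaction
    Prediction from Language-Model Embeddings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts protein-protein interactions from fixed-length
    protein language-model embeddings with a quad-stream attention
    network: per-protein, element-wise product and absolute difference
    feature streams pass through gated multi-head self-attention blocks,
    exchange information through bidirectional cross-attention, and are
    fused for four jointly trained task heads (interaction probability,
    prediction uncertainty, binding strength, interaction type). Includes
    robust median/IQR scaling and Gaussian-noise augmentation of
    embeddings, deduplication, class balancing and two-stage stratified
    splitting of pair datasets, a seeded synthetic benchmark generator
    with a planted bilinear interaction rule, training with
    Adam/AdamW/RMSprop and learning-rate schedules, standard
    classification metrics, and exact nonparametric validation statistics
    (2x2 chi-square with effect sizes, exact Wilcoxon signed-rank test).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
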