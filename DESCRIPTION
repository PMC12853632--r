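Package: presrec
Title: Cross-Domain Neural Collaborative Filtering for Herbal Prescription
    Recommendation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Recommends multi-herb prescriptions from patient symptom sets by
    neural collaborative filtering over cross-domain symptom and herb
    embeddings. Two disease-specific clinical corpora (a source and a target
    domain) are reduced to herb-by-symptom co-occurrence matrices; denoising
    autoencoders and an adversarial correlation-pattern predictor learn
    noise-reduced embeddings in a shared latent space; a two-branch multilayer
    perceptron scores every candidate herb per patient. Ships micro-averaged
    top-K ranking metrics, network-pharmacology proximity statistics
    (separation score, randomization z-score, average shortest path length,
    and an inter-set edge permutation test with binomial significance) on
    protein-protein interaction graphs, and a seeded generator of synthetic
    two-domain clinical corpora and interaction graphs for fully offline
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    Matrix,
    methods,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
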