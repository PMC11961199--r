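Package: catsite
Title: Catalytic Residue Prediction from Enzyme Structure Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts enzyme catalytic residues from atomic structures by
    building residue-level contact graphs attributed with evolutionary
    profiles (PSSM and profile-HMM features), protein language-model
    embeddings, and averaged atomic descriptors, and scoring residues with
    a three-layer graph convolutional network fused through a multilayer
    perceptron. Training mixes an enzyme-class triplet-margin contrastive
    objective with class-weighted supervised learning under a dynamic
    schedule. Includes residue-level evaluation metrics (precision, recall,
    F1, Best-F1, AUC, AUPR), spatial-cohesion analysis of catalytic sites,
    binarization of multiplexed variant-effect (MAVE) scores by the
    intersection of a three-component Gaussian mixture, a tree-structured
    mutation-tolerance triage model, and a fully synthetic data generator
    that plants spatially clustered catalytic residues so the entire
    pipeline is testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    cluster,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    mclust,
    purrr,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
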