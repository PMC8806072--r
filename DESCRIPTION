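Package: circrbp
Title: Prediction of circRNA-RBP Interaction Sites with an Ensemble
    Multiscale Residual Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts RNA-binding-protein (RBP) interaction sites on circular
    RNAs from fixed-length (101 nt) sequence windows. Five complementary
    sequence encodings (k-nucleotide frequencies, paragraph-vector embeddings
    of 10-mer words, electron-ion interaction pseudopotential, nucleotide
    chemical properties, accumulated nucleotide frequency) feed a multiscale
    residual convolutional network with a bidirectional GRU and sigmoid
    self-attention, trained with Adam and combined by AdaBoost into a
    weighted ensemble classifier. Includes FASTA preprocessing (window
    extraction, redundancy filtering, stratified splitting), a
    motif-planting synthetic data generator for end-to-end verification
    without external downloads, evaluation metrics (SE, SP, ACC, MCC, ROC
    AUC), and a command-line pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
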