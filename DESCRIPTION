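Package: utrforge
Title: Model-Guided Engineering of 5'UTRs for Translation Efficiency
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for engineering 5' untranslated regions (5'UTRs) that tune
    mRNA translation. Processes polysome-profiling massively parallel reporter
    assay (MPRA) data into per-variant Mean Ribosome Load (MRL) tables, fits
    sequence-to-MRL predictors (a configurable convolutional network, a
    positional 3-mer linear model, and a Lasso-selected k-mer oracle), designs
    new 5'UTRs by gradient-based optimization (Fast SeqProp) and generative
    exploration networks with optional variational-autoencoder likelihood
    regularization, and analyses downstream mRNA behaviour (spike-in calibrated
    decay kinetics, ribosome-free fraction ratios, gene-editing efficiency
    summaries). A seeded synthetic-data module with a planted ground-truth
    sequence model makes every pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    Matrix,
    methods,
    glmnet,
    Biostrings,
    minpack.lm,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
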