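Package: gpcalib
Title: Calibrated Deep-Learning and GBLUP Genomic Prediction for Multi-Environment Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome-enabled prediction of continuous crop traits in
    multi-environment trials, with a post-hoc calibration step for neural
    network predictions. Implements the VanRaden genomic relationship
    matrix, a REML-fitted GBLUP mixed model with genotype-by-environment
    interaction, a dense feed-forward network (ReLU hidden layers, linear
    output, dropout) tuned over a fixed eight-point hyperparameter grid,
    and three record-level five-fold cross-validation protocols: plain
    GBLUP, the conventional deep-learning workflow (tune, refit, predict),
    and a calibrated workflow that fits an ordinary-least-squares line of
    observed on predicted values from a held-out validation slice and
    applies it to test predictions. A synthetic multi-environment trial
    simulator with known variance components makes the full benchmark
    reproducible without external data.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
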