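Package: infocascade
Title: Noise Propagation and Information Flow in a Stochastic
    Transcriptional Cascade
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Models how the half-life of a stochastically expressed
    transcriptional activator shapes the coordinated diversity of its
    downstream targets.  Provides an Ornstein-Uhlenbeck cascade simulator
    (Euler-Maruyama and exact linear-Gaussian updates), closed-form
    second-moment, mutual-information and information-rate analytics, a
    dividing-microcolony synthetic-data generator emulating single-cell
    time-lapse experiments, and an estimation pipeline computing
    coefficients of variation and Kraskov k-nearest-neighbour mutual
    information binned by microcolony size.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    Matrix,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
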