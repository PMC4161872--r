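Package: pbem
Title: Biophysical Binding-Energy Models and Quality Control for Protein-Binding Microarrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing protein-binding microarray (PBM) experiments:
    principal-component quality-control ellipses with Hotelling T-squared limits
    for single arrays (MA plots) and paired arrays (8-mer median intensities);
    a biophysical model of transcription-factor-DNA binding in which a
    position-specific energy matrix, optionally extended with adjacent
    dinucleotide energy corrections, drives a Fermi-Dirac occupancy summed
    over probe windows; sparse Bayesian learning of the model parameters
    by resilient backpropagation with evidence-approximation hyperparameter
    updates; fuzzy neural-gas classification of arrays into quality groups;
    affinity scanning of genomic peak sequences with regression against
    ChIP-seq tag counts; and synthetic PBM generators with known ground truth
    for validating every step.
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
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    stringi,
    tibble,
    utils
Suggests:
    Biostrings,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
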