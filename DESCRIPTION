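Package: fecalproteo
Title: Label-Free Metaproteomics of Two-Cohort Fecal Microbiomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis pipeline for label-free fecal metaproteomics
    comparing two patient cohorts. Groups protein sequences at a 95 percent
    identity cutoff, maps peptide MS1 intensities to protein groups with
    shared-peptide exclusion and a simplified match-between-runs step,
    applies explicit missing-value filtering and a calibrated generalized-log
    normalization, performs empirical-Bayes moderated differential testing
    with Storey q-values, computes count-based and intensity-weighted Gene
    Ontology relative abundance and hypergeometric enrichment, profiles
    peptide taxonomy by lowest common ancestor, and estimates the "dark
    peptidome" (peptide-like MS2 spectra without database assignments) by
    reconciling de novo and database peptide-spectrum matches. Ships a
    seeded synthetic-data generator that emulates the statistical structure
    of the real inputs so every stage is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    stats,
    utils,
    generics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    Biostrings
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
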