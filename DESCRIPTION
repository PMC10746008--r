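Package: ecotypesim
Title: Ecotype Demarcation for 16S rRNA Surveys by Stable-Ecotype-Model Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for delimiting putative bacterial species (ecotypes and
    geotypes) from aligned 16S rRNA gene fragments. Computes pairwise and
    Jukes-Cantor-corrected distance matrices, summarizes an alignment as a
    binning curve (sequence clusters versus identity criterion), fits the
    three parameters of the Stable Ecotype Model (ecotype formation rate,
    periodic selection rate, number of ecotypes) by Monte-Carlo coalescent
    simulation and Nelder-Mead search with profile confidence intervals, and
    recursively demarcates clades of a rooted phylogeny whose maximum
    likelihood ecotype number equals one. Also provides in-silico PCR with
    IUPAC-degenerate primers, restriction digestion with RFLP typing,
    fragment-based average nucleotide identity between genomes, permutation
    tests of clade-by-environment association, and seed-deterministic
    synthetic-data generators for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    phangorn,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
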