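Package: olfactoR
Title: Olfactory Receptor Repertoire Mining and Molecular Evolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Mines olfactory receptor (OR) open reading frames from fragmented
    genome assemblies, classifies each locus as intact, partial, pseudogene or
    contig-edge truncated, profiles the conserved GPCR motifs, transmembrane
    architecture and per-column conservation of the family, places genes in
    clades with neighbor-joining trees and bootstrap monophyly tests, and
    detects per-site positive selection with counting (SLAC) and fixed-effects
    likelihood (FEL) methods under recombination-aware alignment partitioning.
    A synthetic-data module generates contigs with planted gene repertoires and
    codon alignments with known site-specific dN/dS and recombination
    breakpoints, so every stage of the pipeline is testable with ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    ape,
    Biostrings,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    stringr,
    readr,
    ggplot2,
    generics,
    yaml,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    Matrix,
    jsonlite
Config/testthat/edition: 3
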