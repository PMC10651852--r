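Package: polyagrammar
Title: Nucleotide-Resolution PolyA Site Identification, Strength and Motif Grammar
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Identifies cleavage and polyadenylation (polyA) sites at
    nucleotide resolution from 3' end sequencing reads and from sequence
    alone.  Calls expressed polyA sites from polyA-site-supporting (PASS)
    reads with 24-nt clustering and expression filters; trains a dual-head
    convolutional + bidirectional LSTM classifier ('PolyaID') that emits a
    site probability and a 50-nt cleavage probability vector, and a
    companion regression model ('PolyaStrength') for relative site usage;
    scans genomic sequence one nucleotide per step and consolidates
    predictions into putative sites; scores hexamer motif importance by
    replacement mutagenesis; quantifies cleavage heterogeneity with a
    Shannon entropy statistic; fits logistic models for intronic and
    terminal-exonic site usage from gene-structure features; and annotates
    variant effects on polyA signals.  A synthetic-data generator with a
    configurable motif grammar provides ground-truth genomes, reads and
    variants so the whole pipeline trains and validates at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    stringr,
    ggplot2,
    generics,
    stats,
    utils,
    Biostrings
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    glmnet,
    Rsamtools,
    rtracklayer,
    GenomicRanges,
    IRanges,
    optparse
Config/testthat/edition: 3
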