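Package: bloomcorrect
Title: Counting-Free Sequencing Error Correction with Paired Bloom Filters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Corrects substitution errors in short sequencing reads without
    counting k-mers. A random subsample of read k-mers is stored in one Bloom
    filter; a per-position binomial trust test against that sample identifies
    solid k-mers, which are stored in a second Bloom filter; a greedy
    substitution procedure then edits each read toward the solid k-mer set.
    Includes a position-dependent-error read simulator with full ground-truth
    tracking, recall/precision/gain evaluation of corrections, blocked Bloom
    filter primitives, and the closed-form subsampling model (subsample-hit
    probability, false-positive adjustment, and binomial trust thresholds).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    S4Vectors,
    tibble,
    dplyr,
    ggplot2,
    generics,
    rlang,
    jsonlite,
    readr,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
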