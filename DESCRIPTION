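Package: splicescan
Title: Splice Site Prediction on Genomic DNA with a Convolutional Network
    and Iterative Hard-Negative Mining
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Ab initio localization of donor and acceptor splice sites on
    genomic DNA. A three-class convolutional network (donor / acceptor /
    non-splice-site) is trained on fixed-length one-hot encoded windows
    centered on annotated exon boundaries, rebalanced to a 10:1
    canonical:non-canonical ratio, and sharpened by an iterative
    dataset-reconstruction loop that scans annotated genes, harvests the
    model's false positives into the negative set and retrains. Sites on
    long sequences are called with a single-nucleotide sliding window and
    optionally confirmed by two binary filter networks. Includes FASTA/GTF
    I/O, a synthetic-genome simulator with position-weight-matrix splice
    motifs and configurable non-canonical (GC-AG / AT-AC) junctions,
    classification and false-positive-at-recall evaluation, and
    gradient-times-input contribution profiles with sequence-logo matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
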