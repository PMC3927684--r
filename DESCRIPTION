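Package: kmermap
Title: Genome Mappability and Redundancy from Canonical k-mer Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies how read length limits unique alignment to a
    reference genome. Partitions a genome on assembly gaps or on
    soft-masked repeats, counts canonical (strand-collapsed) k-mers at
    read-length scales (k from tens of bases to 1000 and beyond) with an
    in-memory or disk-bucketed counting engine, and summarises redundancy
    as the non-singleton token proportion and the maximum k-mer frequency
    as functions of k. Fits piecewise power laws to the mappability curve,
    characterises frequency and rank-frequency (Zipf) distributions with
    power-law, Weibull, quadratic-logarithmic and reverse-Beta
    regressions, and locates, merges and annotates the genomic regions
    carrying the highest-frequency long k-mers. A synthetic-genome
    simulator with transposable-element families, tandem repeats,
    segmental duplications and assembly gaps makes the whole pipeline
    testable without external data.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    methods,
    jsonlite,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    stringi,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
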