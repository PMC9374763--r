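Package: trfkit
Title: Small-RNA-Seq Quantification of tRNA-Derived Fragments with
    Hierarchical Read Annotation and Odds-Ratio Meta-Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for discovering and quantifying
    tRNA-derived small-RNA fragments (tRFs) from single-end small-RNA
    sequencing libraries: 3' adapter read-through trimming, sequential
    precedence classification of reads into genomic categories
    (miRNA through repeats) with count-and-remove semantics,
    mismatch-bounded ungapped fragment counting with library-size
    scaling, full-length tRNA counting, and read-length profiles.
    Includes reverse-complement duplex scanning of a fragment against
    3'UTR sequences, luciferase-reporter oligo annealing checks, oligo
    provenance verification, a synthetic-data generator with ground
    truth for dose-series libraries, and 2x2 odds-ratio meta-analysis
    (Mantel-Haenszel, inverse-variance, DerSimonian-Laird) with an
    I-squared-driven fixed/random model switch.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
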