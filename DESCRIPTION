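Package: ont16s
Title: Long-Read 16S rRNA Consensus-Based Bacterial Isolate Identification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements an end-to-end identification pipeline for long-read 16S
    rRNA amplicon sequencing of bacterial isolates: quality filtering of reads,
    dominant-genus screening of a random read subsample against a centroid-style
    reference database, genus-profile construction by center-star alignment,
    per-position frequency-matrix consensus calling with an interpretation
    cutoff and minimum depth, reference matching with BLAST-like identity
    accounting, and CLSI-style interpretation of the identification level
    (species/genus/family/no identification). Also provides the read-subset
    consensus-stability analysis (Hamming distance to the all-reads consensus),
    paired-method comparison statistics (exact McNemar test, concordance), and
    a synthetic-data generator for reference databases, nanopore-like long
    reads and Sanger-like short fragments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    stringr,
    readr,
    ggplot2,
    generics,
    jsonlite,
    withr,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
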