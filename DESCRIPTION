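Package: spliceflow
Title: Phasing-Path-Preserving Transcript Assembly from Spliced Long-Read
    Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reference-based transcript assembly for single-molecule long
    reads (e.g. PacBio CCS). Builds boundary-aware splice graphs from spliced
    alignments and full-length/non-full-length read classifications, represents
    each long read as a phasing path over partial exons, and decomposes every
    splice graph into weighted source-to-sink paths that preserve all phasing
    paths while fitting edge weights by linear programming. Includes
    single-linkage post-assembly clustering of nearly redundant isoforms,
    GTF input/output, intron-chain evaluation metrics (sensitivity, precision,
    PR-AUC, base-level matched/assembled fractions), and a truncation-aware
    long-read simulator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    boot,
    Biostrings,
    dplyr,
    generics,
    GenomicAlignments,
    ggplot2,
    igraph,
    IRanges,
    purrr,
    readr,
    rlang,
    Rsamtools,
    rtracklayer,
    S4Vectors,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    knitr,
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
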