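Package: kincrac
Title: Quantitative Analysis of Kinetic CRAC Time Courses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for time-resolved UV cross-linking (kinetic CRAC / CLIP)
    experiments that sample protein-RNA interactions on a minute time scale
    after a stress shift. Implements read-level processing (demultiplexing by
    in-read barcodes, random-barcode duplicate collapsing, multimapper
    placement, strand-aware pileups, FPKM tables), two-step time-course
    normalization, a Gaussian-process Bayes-factor test for transcripts whose
    binding dynamics differ between a control and a treated time series,
    escape-index screening for transcription attenuation, binding-site (peak)
    calling with permutation false discovery rates, detection of non-encoded
    oligo(A) tails, temporal-profile filtering and K-means clustering,
    TSS-aligned matrices and length-normalized meta-profiles, and a seeded
    synthetic-data generator so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    Biostrings,
    GenomicRanges,
    IRanges,
    jsonlite,
    rtracklayer,
    S4Vectors,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
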