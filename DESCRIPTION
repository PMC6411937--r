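Package: riboqc
Title: Quality Control and Digestion Diagnostics for Ribosome Profiling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Diagnoses RNase digestion completeness in ribosome profiling
    (ribo-seq) libraries from sequence-level footprint metrics: per-position
    nucleotide composition, windowed GC content, footprint length
    distributions, reading-frame periodicity, P-site offsets, region
    (5'UTR/CDS/3'UTR) assignment and metagene coverage. Includes barcode
    demultiplexing, UMI extraction, 3' adapter trimming and UMI-based PCR
    duplicate marking; RNase titration-series planning and GC/length versus
    log-concentration correlation analysis with an optimal-condition
    recommendation; gene-level expression QC (trimmed-CDS counting,
    low-count filtering, size-factor normalisation, pairwise correlation,
    top-variable-gene PCA, hypergeometric gene-set overlap); and a synthetic
    footprint simulator with an explicit digestion-completeness model that
    emits FASTQ plus ground truth, so every metric is testable without
    sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    stringr,
    readr,
    ggplot2,
    jsonlite,
    stats,
    utils,
    generics,
    Biostrings,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    rtracklayer,
    GenomicRanges,
    optparse
Config/testthat/edition: 3
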