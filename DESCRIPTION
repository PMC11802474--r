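Package: seqscope
Title: Streaming Quality Control for Short- and Long-Read Sequencing Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Streaming quality-control engine for Sanger FASTQ (plain or
    gzip-compressed, single- or paired-end) and unaligned BAM sequencing
    data. Computes per-position base content and quality profiles, per-read
    GC and length distributions, and per-read mean quality via the expected
    error rate (with a naive arithmetic-averaging mode for comparison);
    detects adapters with a multi-pattern 12 bp probe scan and, for
    paired-end data, infers insert size and adapter position from read
    overlap; estimates sequence duplication from 16 bp read fingerprints by
    adaptive hash-threshold sampling; flags overrepresented sequence
    fragments by 1-in-8 read sampling and identifies them against a
    contaminant database using canonical k-mer candidate gathering and
    Smith-Waterman alignment; and reports Illumina per-tile quality and
    Oxford Nanopore per-channel activity and translocation speed. Results
    are aggregated into a serializable report with JSON and self-contained
    HTML output, plus a deterministic synthetic-read generator for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    Biostrings,
    Rsamtools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
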