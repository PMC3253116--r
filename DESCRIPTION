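Package: astiler
Title: Strand-Specific Tiling-Array Analysis of Antisense Transcription
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for strand-specific transcriptome analysis on two-strand
    genome tiling microarrays, built around the question of how long
    antisense RNAs repress meiotic genes in vegetatively growing fission
    yeast. Provides probe-to-genome exact mapping, probe-effect and
    background normalization against a genomic-DNA hybridization channel,
    optimal least-squares change-point segmentation of per-strand probe
    signal, segment classification into sense/antisense/non-annotated
    categories, antisense RNA calling with origin classification (discrete
    unit versus 3'UTR extension of a convergent neighbor), per-gene
    strand-specific expression over the CDS span, an intron/exon splicing
    index, gene-group selection and differential statistics with
    hypergeometric enrichment, IUPAC motif scanning (e.g. the forkhead
    motif GTAAAYA) with antisense-origin proximity analysis, exhaustive
    common k-mer discovery, and a fully seeded synthetic-data generator
    that emulates the relevant transcript architectures for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    graphics,
    methods,
    stats,
    utils,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
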