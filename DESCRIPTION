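Package: apacall
Title: Alternative Polyadenylation Site Calling and Differential Usage from
    3'-Terminus Sequencing Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for alternative polyadenylation (APA)
    analysis of whole-transcriptome termini-site sequencing (WTTS-seq style)
    reads: quality filtering and leading poly-T trimming, exact-match read
    mapping or SAM ingestion, extraction of polyadenylation-adjacent sites,
    single-linkage clustering of sites within a fixed nucleotide window,
    strand-aware six-class genomic annotation of predicted APA sites against
    a GFF3 gene model (exonic, distal, extended distal, extended exonic,
    intronic, antisense), negative-binomial Wald testing of differential APA
    usage between two conditions with median-of-ratios normalization and
    Benjamini-Hochberg correction, and chi-square comparison of class-code
    distributions.  Includes a fully deterministic synthetic-data generator
    (toy genome, gene annotation, planted APA truth sites, simulated FASTQ
    reads) so the whole pipeline can be exercised against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
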