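Package: mpracall
Title: Allelic Regulatory Variant Calling for Massively Parallel Reporter Assays
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: An end-to-end analysis pipeline for barcoded massively parallel
    reporter assays (MPRA): oligo library design from variant records,
    barcode-to-oligo association from paired-end reads, per-sample barcode
    quantification with a Levenshtein constant-region filter,
    negative-binomial activity calling of enhancer and silencer alleles
    against plasmid controls, allelic activity testing between reference and
    nonreference alleles, resampling-based enrichment of variant sets in
    ChIP-seq peak datasets, and direction-matched eQTL gene annotation with
    gene-set over-representation. Includes a synthetic-data generator that
    plants known enhancer, silencer and allelic effects so every stage can be
    validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    GenomicRanges,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    DESeq2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
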