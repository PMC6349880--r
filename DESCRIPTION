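Package: nad4c
Title: Multi-Bait 4C-seq Analysis of rDNA-Genome Interactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A desk-scale pipeline for analysing chromatin interactions
    between the ribosomal DNA (rDNA) and the rest of the genome from
    multi-bait 4C-seq count data, as used to map nucleolar-associated
    domains (NADs) across malignant progression. Provides in-silico
    restriction digestion and 5-kb window tiling, bait-level filtering
    (bait-support, single-bait outlier, replicate observation),
    median-of-ratios library normalization, a conditional negative-binomial
    exact test with BH false-discovery control, constitutive/differential
    window classification, reciprocal (UBTF-dependent) class-switch
    detection, nearest-TSS gene annotation, expression integration with
    Kolmogorov-Smirnov comparisons, peak/region overlap statistics with a
    bootstrap null, closed-form bench-assay arithmetic (qPCR, ChIP, HpaII,
    MeDIP, 3C, psoralen), and a synthetic-data generator with a ground-truth
    ledger for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    graphics,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    DESeq2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
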