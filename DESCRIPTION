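Package: txatlas
Title: Characterization of Multi-Tissue Transcriptome Atlases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to characterize a bulk RNA-seq expression atlas across many
    cell and tissue types: GTF annotation parsing with a transcript-biotype
    census, TPM-threshold expression calling with replicate averaging,
    median-of-ratios count normalization, tissue-specificity scoring by
    Shannon entropy, detection of opposite-strand gene relations (overlapping
    antisense pairs and head-to-head promoter pairs) with per-tissue
    co-expression and mono-expression status, and isoform-per-gene summary
    statistics. Includes a synthetic-data generator that plants antisense
    pairs, head-to-head pairs, tissue-specific genes and high-isoform genes
    with full ground truth, so every pipeline stage can be validated by
    parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils
Suggests:
    DESeq2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
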