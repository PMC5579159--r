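Package: dipseqr
Title: Segmentation and Differential Analysis of DNA (Hydroxy)Methylation DIP-Seq Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis chain for MeDIP-seq and hMeDIP-seq (DIP-Seq) tag data:
    sliding-window tag counting with a Monte-Carlo permutation background model
    to segment 5mC/5hmC enriched regions, negative-binomial differential region
    testing with FDR control (Benjamini-Hochberg and Storey q-values), gene
    annotation of regions against TSS windows and gene boundaries, detection of
    genes carrying both up- and down-regulated hydroxymethylation regions with
    gene-body density statistics and permutation tests, direction-stratified
    Fisher overlap analyses, in-silico replicate pooling, K-means profiling,
    and metagene density visualization. Includes a synthetic-data generator
    with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
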