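Package: mirslam
Title: Quantification of Newly Synthesized miRNAs from Nucleotide-Conversion Small RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Implements a metabolic-labeling (SLAMseq-style) quantification
    pipeline adapted to mature microRNAs: simulation of labeled NEXTflex-style
    small-RNA libraries with ground truth, adapter and randomized-base
    trimming, conversion-aware assignment of reads to mature miRNA features
    with SNP masking, per-miRNA T>C conversion rates and CPM, expression and
    above-background labeling filters, and a background-subtracted synthesis
    ratio contrasting a drug treatment with its vehicle control, together
    with genomic-context group comparisons and TSS-distance correlation.
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
    Rcpp,
    methods,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
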