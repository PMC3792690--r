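Package: chirpflow
Title: Downstream Analysis of ChIRP-Seq Peak Sets
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Reproducible downstream analysis of chromatin isolation by RNA
    purification sequencing (ChIRP-seq) peak calls: quality filtering on
    fold-enrichment and false discovery rate, windowed replicate-consensus
    peak identification, negative-control proximity screening, closest-gene
    assignment with TSS-distance profiling, and chi-squared gene-set overlap
    enrichment against differential-expression results. Includes a synthetic
    data generator with planted ground truth so every stage of the pipeline
    can be validated end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
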