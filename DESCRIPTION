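Package: tapecall
Title: Transcriptionally Active Putative Enhancer Identification from
    Chromatin Accessibility and Stranded RNA Coverage
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Identifies transcriptionally active putative enhancers (TAPEs)
    by intersecting ATAC-seq regions of open chromatin with bidirectional,
    strand-specific RNA coverage; predicts enhancer-gene regulatory pairs by
    Pearson correlation of CPKM expression within a 1 Mb window; calls
    region-selective and activity-dependent enhancers with a
    negative-binomial differential test and z-score clustering; and ships a
    fully seeded synthetic-data generator with planted ground truth so every
    stage of the pipeline can be validated end to end without sequencing
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    BiocGenerics,
    Biostrings,
    MASS,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
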