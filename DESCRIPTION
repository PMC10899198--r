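Package: mpracall
Title: Enhancer and Allele-Specific Variant Calling for Massively
    Parallel Reporter Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: End-to-end quantification of massively parallel reporter
    assays (MPRA): design of allele-paired 230 bp oligo libraries around
    single-nucleotide variants, recovery of barcode-to-oligo pairings
    from paired-end association sequencing, guide-anchored barcode
    counting in DNA and RNA libraries across replicates, element-level
    aggregation with cross-replicate presence and minimum-barcode
    filters, z-score calling of general enhancers from log2 RNA/DNA
    activity ratios, and an empirical-Bayes moderated paired linear
    model for allele-specific enhancer calling with Benjamini-Hochberg
    tiering. Includes downstream annotation arithmetic (depletion-rank
    window means, transcription-factor binding-site delta-score
    thresholding, flanked interval overlap, k-group proportion tests)
    and a synthetic-data generator with planted ground truth for
    end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    methods,
    stats,
    utils,
    graphics,
    yaml
Suggests:
    limma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
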