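Package: cfrca
Title: Rolling-Circle Consensus Calling and Multimodal Tumor Fraction
    Estimation for Nanopore Cell-Free DNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Toolkit for rolling-circle-amplification (RCA) concatemer
    sequencing of cell-free DNA (cfDNA): per-position majority-vote
    consensus calling with quality aggregation, backbone trimming and
    coordinate deduplication; sequencing error-rate measurement with
    germline masking and Phred conversion; tumor-informed single
    nucleotide variant (SNV) allele counting with a Monte Carlo
    grid-search tumor-fraction estimator; fragment-length fragmentomics
    with a fixed-signature nonnegative matrix factorization tumor-fraction
    estimator; and an in-silico limit-of-detection simulator across
    sequencing platform presets. All inputs can be generated by a fully
    seeded synthetic-data module that emulates bimodal nucleosomal cfDNA
    fragment lengths, tumor fragment shortening with 10-bp periodicity,
    concatemer subread stacks with substitution errors, and tumor/healthy
    cfDNA admixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    pracma,
    withr,
    yaml,
    vcfR,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
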