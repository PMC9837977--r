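Package: enhancerConcord
Title: Concordance Analysis of Activity-Defined and Chromatin-Defined Enhancer Sets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies agreement between enhancer interval sets defined by
    reporter-gene activity and sets defined by chromatin-level assays
    (ATAC-seq, ChIP-seq and related). Provides BED interval handling,
    single-basepair overlap counting with unique query reporting, a
    genome-shuffle permutation null with z-score significance and
    enrichment/depletion classification, per-enhancer found-vector
    correlation (phi) matrices for batch-effect detection, consensus peak
    merging with a support threshold, and a synthetic enhancer-universe
    generator with known sensitivity, false-positive and batch structure
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pheatmap
Config/testthat/edition: 3
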