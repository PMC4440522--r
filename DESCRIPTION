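Package: gepa
Title: Gene Expression Pattern Analysis Across Multiple Cell States
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Deterministic classification of gene expression patterns across
    two or more cell states. Each gene is sorted by expression and scanned for
    the first consecutive fold change at or above a threshold; genes are
    assigned a single- or multi-state enrichment pattern, or the sentinel
    categories "Gradient" and "Even". Includes the FPKM preprocessing chain
    (isoform-to-gene aggregation by quality status, all-zero filtering,
    per-sample normalization to a fixed total, pseudocount), threshold
    calibration against negative and positive control gene lists, a shuffled
    matrix null control, external-list category mapping, percent-of-sum
    specificity profiles, isoform-switch detection, annotation subsetting,
    synthetic fixture generators with known ground truth, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
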