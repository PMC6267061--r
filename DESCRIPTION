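Package: entiresist
Title: Expression Signatures, Copy-Number Segmentation and Network Ranking
    of HDAC-Inhibitor Resistance Drivers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for identifying candidate driver genes of
    HDAC-inhibitor resistance in luminal breast cancer models:
    permutation-based two-class differential expression (SAM-style),
    derivation of gene signatures from correlation-based centroid-linkage
    clustering under a node-correlation rule, median signature scoring,
    F-statistic segmentation of aCGH probe tracks with gene-level
    gain/loss calls, per-sample network-propagation driver ranking with
    percentrank aggregation, and survival stratification by signature
    tertiles or deletion status. Includes a synthetic-cohort generator
    with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    igraph,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
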