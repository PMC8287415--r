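Package: dyspathway
Title: Dysregulated Pathway Identification from Gene-Pair Differential
    Co-Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies dysregulated biological pathways from two-group
    expression data by scoring every gene pair of a combined gene-pair
    background with a per-sample correlation-by-individual-level-product
    (CILP) statistic summarised as a Welch two-sample t score (DysGPS),
    ranking all background pairs, and testing each pathway's gene-pair set
    with a weighted Kolmogorov-Smirnov running-sum enrichment score (DysPS).
    Significance is assessed by sample-label permutation with a null shared
    across pathways, Benjamini-Hochberg false-discovery-rate control, and a
    gain/loss-of-correlation direction call. Includes builders for combined
    observed-plus-random gene-pair backgrounds, readers and writers for the
    pair-level file formats involved, a bivariate-normal simulation engine
    with ROC/AUC evaluation of detection power, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
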