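Package: aicmax
Title: Information-Theoretic Selection of Molecular Fingerprint Bits Across
    Multiple Targets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Greedy selection of the most informative molecular fingerprint
    bits for ligand activity classification against one or several biological
    targets. Ranks feature subsets by their Average Information Content (AIC),
    the entropy-normalized mutual information between a set of binary
    fingerprint bits and each target's activity labels, averaged over targets,
    so that per-target compound sets may differ. Provides the greedy AIC-Max
    selector with an optional random-subsample conditioning heuristic, an
    exhaustive best-subset oracle for small instances, k-fold cross-validated
    evaluation of reduced representations by Matthews correlation coefficient
    and held-out normalized mutual information, a synthetic multi-target data
    generator with planted ground truth, and CSV/JSON readers and writers for
    bit matrices, activity labels and multi-target manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    tibble,
    tidyr,
    utils,
    stats,
    withr
Suggests:
    randomForest,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
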