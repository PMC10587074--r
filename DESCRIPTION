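Package: potencybench
Title: Benchmarking Compound Potency Prediction with Potency Sub-Range Diagnostics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for diagnosing what compound potency regression benchmarks
    actually measure. Implements Tanimoto-kernel support vector regression,
    random forest regression, nearest-neighbour and median-regression controls
    over binary molecular fingerprints, the train/test protocols used in
    ChEMBL-style activity-class benchmarks (random 50/50 trials and
    sub-range-balanced training-set ladders), error decomposition by pIC50
    sub-range, Wilcoxon signed-rank method comparisons, and a synthetic
    structure-activity-relationship generator so the whole pipeline runs
    without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    kernlab,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    ChemmineOB,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
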