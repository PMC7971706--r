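Package: gazeinfo
Title: Information-Theoretic Analysis of Eye-Movement Scan Paths
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Quantifies the predictability of AOI-coded eye-movement scan
    paths. Implements plug-in estimators of gaze transition entropy (GTE)
    and active information storage (AIS) with data-driven, per-individual
    optimization of the predictive past state (non-uniform embedding via
    greedy forward selection with max-statistic permutation testing),
    per-fixation local measures, preprocessing and trial-period labelling
    of fixation records, a higher-order Markov scan-path simulator with an
    exact analytic oracle, and a contrast-coded linear mixed-model stage
    for task-period and difficulty effects.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    lme4,
    lmerTest,
    Matrix,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
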