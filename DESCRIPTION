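Package: breakscan
Title: Chromosomal Breakpoint Counting and Prognostic Classification from
    Copy-Number Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies tumor genomic instability from SNP-array copy-number
    profiles by exact least-squares change-point segmentation (naive and
    pruned dynamic programming) with modified-BIC selection of the number of
    breakpoints, including a first-round screen that discards single-probe
    outlier segments. Turns genome-wide breakpoint counts into a prognostic
    classifier via Youden-index threshold training with ROC/AUC (DeLong
    confidence intervals), computes proliferation comparators (genomic grade
    index with -1/+1 standardization, KI67 dichotomization, IHC3 score), and
    validates prognostic value with Kaplan-Meier, log-rank and Cox
    proportional-hazards analyses. Ships seeded synthetic-data generators for
    probe-level profiles and survival cohorts so the whole pipeline is
    testable without array data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Rcpp,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
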