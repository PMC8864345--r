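Package: replimeta
Title: Comparing Meta-Analytic and Multi-Laboratory Replication Effect Estimates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for confronting random-effects meta-analytic effect size
    estimates with the corresponding multi-laboratory replication (MLR)
    estimates across a collection of phenomena. Implements a self-contained
    random-effects meta-analysis engine (DerSimonian-Laird, Paule-Mandel and
    REML heterogeneity estimators; Wald and Knapp-Hartung intervals),
    calibrated (empirical-Bayes shrunken) estimates of the distribution of
    population effects with a proportion-below-threshold statistic and BCa
    bootstrap confidence intervals, publication-bias sensitivity analysis
    under a significance-based selection model (eta-corrected and worst-case
    pooled estimates), a synthetic-data generator emulating significance-based
    publication selection, and a cross-phenomenon comparison layer with
    correlation and discrepancy summaries. All user-facing functions take
    plain data frames of study-level effect sizes and return tibbles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    readr,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    boot,
    metafor,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
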