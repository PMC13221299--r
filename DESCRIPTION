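Package: pedbc
Title: Body-Composition Reference Curves, Clustering and Health-Risk
    Profiling for Children
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for profiling body composition in school-age children.
    Builds age- and sex-specific reference curves for body-composition
    indices (fat, lean, muscle, bone and total-body-water mass divided by
    height squared) by cubic polynomial regression on per-age bin means and
    standard deviations, and standardizes observations to z-scores against
    those curves.  Screens wrist-worn device traces (activity minutes,
    steps, sleep) with edge-day trimming, wear-time filters and +/-2 SD
    outlier removal.  Handles missing indicator data by k-nearest-neighbour
    imputation, chained-equation multiple imputation with predictive mean
    matching, or complete-case deletion, with Rubin pooling.  Discovers
    body-composition subpopulations by Ward hierarchical clustering (with a
    k-means sensitivity route) after collinearity pruning, and compares
    health indicators across clusters with ANOVA, chi-square tests and
    random-intercept mixed regressions.  A synthetic-cohort generator with
    planted cluster structure, wearable traces and injected missingness
    makes the whole pipeline testable without access to restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    lme4,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
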