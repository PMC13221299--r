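# pedbc — body-composition profiling for children

`pedbc` is an R package for profiling body composition in school-age
children (7–14 years) measured with bioelectrical impedance analysis
(BIA).  It targets a recurring problem in pediatric health screening: BMI
alone cannot distinguish a child whose high weight is muscle from one whose
high weight is fat, yet the second profile carries the metabolic risk.

The pipeline:

1. **Reference curves.**  Each body-composition index (a component mass
   over height squared, kg/m²: FMI fat, LMI lean, MMI muscle, BNI bone,
   TWI total body water, plus BMI) is summarised per sex and integer age
   as bin mean and SD; three score series — mean, mean + 1 SD,
   mean − 1 SD — are each fitted with a cubic polynomial in age.  An
   observation's z-score is `(value − mean(age, sex)) / sd(age, sex)` with
   `sd = (upper − lower) / 2` at the age rounded to 0.1 years.
2. **Wearable screening.**  Daily wrist-device records pass edge-day
   trimming (first/last 3 days), wear-time filters (monitored share
   > 0.8, total-activity share > 0.1, strict), and inclusive ±2 SD bands
   for daily steps and sleep, before per-participant-year means are taken.
3. **Missing data.**  k-nearest-neighbour imputation (main, k = 5),
   chained-equation multiple imputation with predictive mean matching
   (sensitivity; every imputed value is an observed value of its column),
   or complete-case deletion, with Rubin pooling for pooled inference.
4. **Clustering.**  After pruning the near-collinear lean/muscle/water
   trio (|r| > 0.99, MMI kept as representative), Ward hierarchical
   clustering on the z-scores of {BMI, FMI, MMI, BNI} cut at k = 5, with a
   k-means++ sensitivity route and adjusted-Rand agreement.  Canonical
   labelling orders clusters 1–4 by rising overall composition and
   reserves label 5 for the high-fat / average-muscle profile.
5. **Group comparison.**  One-way ANOVA and chi-square tests across
   clusters, plus random-intercept (REML) regressions adjusting for
   cluster, year, sex and age, with exponentiated coefficients and Wald
   intervals.

Because the motivating clinical data are legally restricted, the package
includes a first-class synthetic-cohort generator
(`generate_cohort()`, `generate_device_data()`, `inject_missing()`) whose
defaults encode the study conditions: ~353 children over three annual
waves (~917 observations), exact BIA mass identities
(fat + lean = weight, muscle + bone = lean, water < lean), a planted
five-cluster z-space structure, 11-day device traces with low-wear days,
and missingness at the study's per-measurement rates.

## Worked example

```r
library(pedbc)

cents  <- default_cluster_centroids()
params <- cohort_params(cluster_centroids = cents,
                        cluster_weights = attr(cents, "weights"),
                        seed = 1)
cohort <- add_bci(generate_cohort(params))
nrow(cohort)
#> [1] 923

ref <- build_reference(cohort)           # cubic reference curves
z   <- cohort_zscores(ref, cohort)       # per-child z-scores

zc <- paste0("z_", c("bmi", "fmi", "lmi", "mmi", "bni", "twi"))
round(cor(z[, zc]), 3)[1, ]
#> z_bmi z_fmi z_lmi z_mmi z_bni z_twi
#> 1.000 0.959 0.941 0.936 0.872 0.938

keep <- prune_collinear(z[, zc])         # LMI/MMI/TWI collapse to MMI
keep
#> [1] "z_bmi" "z_fmi" "z_mmi" "z_bni"

cl <- canonical_order(ward_cluster(z[, keep], k = 5))
cl
#> <bc_clusters> ward, k = 5, n = 923
#>    z_bmi  z_fmi  z_mmi  z_bni
#> 1 -1.201 -1.093 -1.190 -1.256
#> 2 -0.536 -0.560 -0.433 -0.583
#> 3  0.311  0.281  0.319  0.252
#> 4  1.318  1.107  1.450  1.261
#> 5  0.951  1.516  0.190 -0.116
```

Reading the output: BMI z-scores correlate far more strongly with fat
(0.959) than with muscle (0.936 via the overall size factor, but 0.800
against FMI's 0.959 once lean indices are compared directly), and the
canonical cluster 5 centroid shows the at-risk signature — fat z ≈ +1.5
with muscle and bone near the average.  Downstream,
`run_comparison_suite()` contrasts body fat percentage, abdominal
circumference, lipid ratios, steps, activity and sleep across the five
clusters.

## Package layout

* `R/synthetic-cohort.R` — cohort/device/missingness generators and their
  parameter object
* `R/reference-model.R` — bin statistics, cubic reference fitting,
  z-scoring, reference-table export, JSON round-trip
* `R/device-screening.R` — epoch aggregation, edge trimming, wear filters,
  ±2 SD bands, participant-year summaries, MVPA compliance
* `R/missing-data.R` — kNN imputation, MICE-PMM, Rubin pooling,
  complete-case filtering, missingness summaries
* `R/clustering.R` — collinearity pruning, Ward and k-means++ clustering,
  canonical labelling, adjusted Rand index
* `R/group-stats.R` — ANOVA, chi-square, Pearson correlation,
  (mixed) regressions and the comparison suite
* `vignettes/body-composition-profiling.Rmd` — the model, its assumptions,
  and the reasoning behind every numerical convention
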