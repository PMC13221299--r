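---
title: "Profiling body composition in children: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling body composition in children: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedbc)
library(dplyr)
```

## The problem

Body weight and BMI summarise a child's size but not its composition: two
children with identical BMI can differ markedly in how that mass splits into
fat, muscle, bone and water.  `pedbc` implements a profiling pipeline for
school-age children (7--14 years) measured annually with bioelectrical
impedance analysis (BIA): build age- and sex-specific reference curves for
body-composition indices, standardize every child to z-scores, discover
subpopulations by clustering in z-space, and ask whether those
subpopulations differ in health indicators (body fat percentage, abdominal
circumference, lipid ratios) and lifestyle measures (steps, activity, sleep)
collected with a wrist-worn device.

A body-composition index (BCI) is a component mass divided by height
squared, in kg/m^2: FMI (fat), LMI (lean), MMI (muscle), BNI (bone) and TWI
(total body water), the same construction as BMI.

## Reference curves and z-scores

For each sex and index, observations are binned by integer age (floor: ages
8.0--8.9 fall in bin 8) and each bin contributes its count, mean and sample
SD (n-1 denominator).  Three score series are formed per sex x index -- the
bin mean and the mean plus or minus one SD -- and each series is fitted with
a least-squares cubic polynomial in integer age.  At evaluation time the age
is rounded to 0.1 years, the mean is the mean-curve value, and the SD is
recovered as `(upper - lower) / 2`.  This symmetric recovery averages the
two one-sided SD estimates; the asymmetry `upper - mean` vs `mean - lower`
remains inspectable from the stored coefficients.  A z-score is then
`(value - mean) / sd`.

Numerical choices worth recording:

* **Binning by floor, not rounding.**  "Integer age" is interpreted as
  completed years, the convention of growth references.
* **Sample SD (n-1)** in bins; bins with fewer than two observations are
  dropped with a warning because they carry no SD.
* **No extrapolation.**  Cubic tails are untrustworthy outside the observed
  ages, so evaluation outside the fitted domain (`[min integer age,
  max integer age + 0.9]`) is an error by default, with an explicit
  `clamp = TRUE` escape hatch.
* **SD floor** of 1e-6 kg/m^2 to keep degenerate fixtures (constant bins)
  from dividing by zero.
* **Height, weight and BMI** are standardized with the same three-curve
  machinery rather than an external national reference tool; the package is
  self-contained by design, at the cost of using internal rather than
  population-wide anthropometric references.
* Reference fitting pools all subject-wave observations by default (a child
  measured three times contributes three observations);
  `first_per_child = TRUE` restricts to first observations.

Serialization uses `%.17g` formatting so a model written to JSON and read
back reproduces bit-identical z-scores.

## The synthetic cohort

Because the underlying clinical data cannot be redistributed, the package
ships a generator whose defaults encode the study conditions the pipeline
expects: about 353 children enrolled, three annual waves with per-wave
participation probabilities 336/353, 318/353 and 263/353 (so roughly 917
subject-wave observations), baseline ages 7.0--11.9 advancing exactly 1.0
year per wave, and sex drawn evenly.

Component masses are built in z-space.  Each subject receives a latent
(FMI, MMI, BNI) z-vector either from a correlated-factor model (a shared
size factor produces the fat--lean correlation) or, when centroids are
supplied, from a five-component mixture with configurable within-cluster SD
(default 0.3) plus a small per-wave jitter (default 0.1) for year-to-year
biological fluctuation.  Index values are `mean_curve(age, sex) +
sd_curve(age, sex) * z`, and masses follow from the generator's BIA
conventions, declared because BIA devices do not publish their internal
identities: `fat + lean = weight`, `muscle + bone = lean`, and
`water = 0.73 * lean` with a small noise term, clipped below lean.  These
identities hold exactly in every generated record, so they can be asserted,
not just expected.  Derived reference curves follow the same conventions
(LMI = MMI + BNI and so on); the SD curves of derived indices are
coefficient-level combinations, exact in the perfectly collinear limit and
a close approximation otherwise.

The default five centroids mirror the reported subpopulation semantics: a
low-everything cluster (most common), two near-average clusters, a
uniformly-high cluster, and a high-fat/average-muscle cluster.  The
clusters sit at realistic, partially overlapping separations -- recovery
against true labels is therefore good but deliberately not perfect.  Tests
of cluster *recovery* instead plant centroids with pairwise separation of
at least 2 z-units and within-cluster SD 0.3, conditions under which both
clustering routes must exceed 0.9 adjusted Rand index.

Health indicators are tied to the fat z-score (abdominal circumference,
total cholesterol and triglycerides rise with it, HDL cholesterol falls,
sleep shortens), while steps and activity minutes carry no composition
signal -- the generator expresses subpopulation differences through
adiposity-linked indicators and sleep only.  Missingness is injected
completely at random at the per-measurement rates of the study design
(abdominal circumference 3/917, lipid panel 110/917 jointly across TC, TG
and HDLC, steps 86/917, activity 134/917, sleep 183/917).

What the generator does **not** emulate: minute-level accelerometer epochs
(only daily aggregates), measurement-date scatter within a wave (ages
advance exactly 1.0 years), growth-curve realism for any specific national
population, and informative missingness.  Passing tests therefore
demonstrate that the machinery is correct under its stated assumptions, not
that any particular real cohort satisfies those assumptions.

All randomness flows from one master seed through labelled streams
(`derive_seed()`), so adding a generator call never perturbs existing
draws.

## Wearable screening

Daily device records pass a sequential screen:

1. **Edge-day trimming**: the first and last 3 calendar days of each
   subject-wave's wear period are dropped (device hand-out/collection days
   are unreliable); weekdays and holidays are otherwise treated alike.
2. **Wear-time filters**: a day is kept only if monitored minutes / 1440
   exceed 0.8 *strictly*, and (light + moderate + vigorous) / 1440 exceeds
   0.1 strictly.  The thresholds are quoted as "greater than", so the
   boundary day fails.
3. **Outlier bands**: daily steps and sleep minutes must lie within the
   mean plus or minus 2 sample SDs, *inclusive* ("within" is read
   inclusively).  The bands are computed in a single pass (no iterative
   re-trimming) over the days that survived the wear filters, cohort-wide
   within each measurement year by default (`sd_scope = "subject"` gives a
   per-participant variant).  Steps are checked before sleep, and the
   exclusion audit records the first failed criterion per day.

Every input day lands in exactly one of retained or excluded; the partition
is order-invariant.  Note that only the *wear-time* stage is monotone in
its threshold -- loosening the 0.8 cutoff can change the downstream SD
bands, so the end-to-end retained set is not nested across thresholds.

Per-participant-year summaries are arithmetic means over retained days;
subject-waves with no retained days get `NA` summaries, which flow to the
imputation stage.  Guideline compliance is the fraction of subject-wave
summaries with mean moderate-to-vigorous activity at or above 60 min/day,
computed on retained days only.

Sleep episodes beginning between 18:00 and midnight are credited to the
following (wake) day; episodes beginning between midnight and noon to the
same day; afternoon starts fall outside the device's recording window and
are dropped with a warning.

## Missing data

Three strategies, mirroring a main analysis and two sensitivity analyses:

* **kNN imputation (main, k = 5).**  The distance contract is explicit so
  that the brute-force oracle in the test suite is well-defined: Euclidean
  over mutually observed features, each scaled by its column SD, inflated
  by `p / |mutual|`, donors restricted to rows with the target observed,
  ties broken by row order, unweighted donor mean.
* **Chained-equation multiple imputation with predictive mean matching
  (sensitivity; m = 20 sets, 50 cycles, 5 donors, seed 1234 by default).**
  Columns are visited in ascending missing count.  Each target is
  regressed on all other columns; sigma-squared is drawn from its scaled
  inverse-chi-squared posterior and coefficients from their Gaussian
  posterior; each missing cell takes the observed value of a donor drawn
  uniformly from the 5 rows with the closest predicted mean (observed rows
  predicted under the posterior mean, missing cells under the draw).
  Every imputed value is consequently an observed value of its own column.
* **Complete-case deletion** over the analysis columns.

Estimates from the multiple-imputation route are pooled with Rubin's
rules; the total variance is the within-imputation mean plus
`(1 + 1/m)` times the between-imputation variance, with Barnard--Rubin
degrees of freedom when a complete-data df is supplied.

## Clustering

Because LMI, MMI and TWI are near-perfectly collinear (|r| > 0.99 in both
real and generated data), features are first pruned: groups are the
transitive closure of the |r| > 0.99 graph and each group keeps one
representative (MMI by convention).  Clustering then runs on the z-scores
of BMI, FMI, MMI and BNI, which are already on a common scale and are not
re-standardized.

The main route is agglomerative clustering with Ward's minimum-variance
criterion on squared Euclidean distances, cut at the last four merges to
give k = 5; reported heights are in squared-distance units.  k is fixed at
five to match the subpopulation structure the pipeline targets; an elbow
diagnostic over other k is provided but no automatic selection, since none
is defined for this design.  A k-means route (Lloyd's algorithm, k-means++
seeding, 10 restarts, best within-cluster SS) serves as the sensitivity
check, and the adjusted Rand index quantifies agreement between the two.
Merge-cost ties are resolved by the underlying agglomeration
implementation; on continuous data ties have probability zero.

Cut labels are arbitrary, so `canonical_order()` assigns the substantive
labels: the three lowest-BMI centroids become clusters 1--3 in ascending
BMI; of the two highest-BMI centroids the higher-MMI one becomes cluster 4
(uniformly high composition) and the other cluster 5 (high fat, average
muscle -- the elevated-risk profile); BMI ties break by ascending FMI.

## Group comparisons

Numeric indicators (body fat percentage, abdominal circumference, TC/HDLC,
TG/HDLC, steps, activity, sleep) are compared across clusters by one-way
ANOVA, and by a regression adjusting for cluster (indicators against
reference cluster 1), measurement year (categorical), sex (boys 0, girls
1) and age (continuous years).  With repeated annual measurements a
Gaussian random intercept per child absorbs within-child correlation and
the model is fitted by REML; the multiple-imputation route fits OLS per
completed dataset (no random intercept) and pools with Rubin's rules.
Demographic composition (sex, year, integer age) is compared by Pearson
chi-square without continuity correction.

Reporting conventions: Wald confidence intervals with residual-approximate
degrees of freedom `n - p`; coefficients and interval endpoints are also
reported exponentiated (the conventional forest-plot axis) without any log
transformation of the outcomes -- `exp(estimate)` is a display transform,
and its interval contains 1 exactly when the raw interval contains 0.  No
multiplicity correction is applied across the indicators; each test uses
alpha = 0.05.  Covariates that are degenerate in a given dataset (a single
measurement year, constant sex) are dropped from the design rather than
producing an unusable model; a single-level cluster term is an error.

## Problem sizes and determinism in the shipped checks

The test suite and the acceptance script regenerate everything from code:
the full pipeline runs at the study scale (~917 subject-wave observations,
11-day traces), reference-recovery simulations use 200 observations per
age-sex bin, imputation oracles use one hundred 50 x 6 matrices, cluster
recovery uses n = 500 with the separated planted centroids, and the ANOVA
type-I calibration uses 100 replicates against a binomial 99% band.  The
self-standardization band (per-bin z means within 0.3, SDs within
(0.7, 1.3)) is checked at roughly 200 observations per bin; at much
smaller bin sizes the band would be crossed by ordinary sampling noise.
Every stochastic step is seeded, and the acceptance script threads a single
`--seed` through labelled streams.

## Known limitations

* The reference curves are internal to the analysed cohort; they are not a
  population growth standard, and no Box--Cox (LMS) machinery is provided.
* The ward/k-means agreement and cluster recovery statements are about the
  generator's geometry; real cohorts have no ground-truth labels.
* PMM uses a fixed donor count (5) and linear conditional models; NMAR
  mechanisms and categorical imputation models are out of scope.
* Exponentiated coefficients of an identity-link model are a reporting
  convention here, not a claim that effects are multiplicative.
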