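test_that("one-way ANOVA matches the hand-worked F statistic", {
  res <- oneway_anova(list(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5)))
  expect_equal(res$statistic, 3)  # SSB = 6, SSW = 6, F = (6/2)/(6/6)
  expect_identical(res$df1, 2L)
  expect_identical(res$df2, 6L)
  expect_error(oneway_anova(list(c(1, 1), c(1, 1))), "zero within-group")
  expect_error(oneway_anova(list(1, 2)), ">= 2 groups")
})

test_that("two-group ANOVA F equals the squared pooled t statistic", {
  withr::with_seed(55, {
    for (rep in 1:5) {
      a <- rnorm(12)
      b <- rnorm(15, mean = 0.4)
      f <- oneway_anova(list(a, b))
      tt <- stats::t.test(a, b, var.equal = TRUE)
      expect_equal(f$statistic, unname(tt$statistic)^2, tolerance = 1e-10)
      expect_equal(f$p_value, tt$p.value, tolerance = 1e-10)
    }
  })
})

test_that("chi-square uses the Pearson statistic without correction", {
  expect_equal(chi_square(rbind(c(10, 10), c(10, 10)))$statistic, 0)
  res <- chi_square(rbind(c(20, 0), c(0, 20)))
  expect_equal(res$statistic, 40)  # all E = 10, four cells of (10)^2/10
  expect_identical(res$df, 1L)
  # 2x3 fixture against the direct O/E computation
  tab <- rbind(c(8, 12, 5), c(4, 9, 14))
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(chi_square(tab)$statistic, sum((tab - E)^2 / E))
  # permutation invariance
  expect_equal(chi_square(tab[, c(3, 1, 2)])$statistic,
               chi_square(tab)$statistic)
  expect_error(chi_square(rbind(c(0, 0), c(1, 2))), "margin")
})

test_that("Pearson correlation handles exact and fixture cases", {
  x <- 1:10
  expect_equal(pearson_cor(x, 2 * x)$estimate, 1)
  expect_equal(pearson_cor(x, -x + 7)$estimate, -1)
  fx <- c(1, 2, 3)
  fy <- c(2, 3, 5)
  expect_equal(pearson_cor(fx, fy)$estimate, direct_pearson(fx, fy))
  # sign-aware affine invariance
  withr::with_seed(2, {
    a <- rnorm(30)
    b <- a + rnorm(30)
    expect_equal(pearson_cor(3 * a - 1, b)$estimate,
                 pearson_cor(a, b)$estimate, tolerance = 1e-12)
    expect_equal(pearson_cor(-2 * a, b)$estimate,
                 -pearson_cor(a, b)$estimate, tolerance = 1e-12)
  })
  expect_error(pearson_cor(c(1, 1, 1), c(1, 2, 3)), "zero variance")
})

sim_longitudinal <- function(n_subj = 200, waves = 3, beta5 = 0.5,
                             sd_subj = 1, sd_eps = 1) {
  cluster <- sample(1:5, n_subj, replace = TRUE)
  b <- rnorm(n_subj, sd = sd_subj)
  rows <- lapply(1:waves, function(w) {
    tibble::tibble(subject_id = sprintf("P%03d", 1:n_subj),
                   cluster = cluster, wave = w,
                   sex = sample(c("male", "female"), n_subj, replace = TRUE),
                   age = runif(n_subj, 7, 12) + w - 1,
                   y = 1 + beta5 * (cluster == 5) + b +
                     rnorm(n_subj, sd = sd_eps))
  })
  dplyr::bind_rows(rows)
}

test_that("the mixed model recovers a planted cluster effect", {
  withr::with_seed(61, {
    d <- sim_longitudinal(n_subj = 200, beta5 = 0.5)
    res <- fit_regression(d, "y")
    row <- res[res$term == "cluster5", ]
    expect_lt(abs(row$estimate - 0.5), 3 * row$se)
    vc <- as.data.frame(lme4::VarCorr(attr(res, "model")))
    sd_subj <- vc$sdcor[vc$grp == "subject_id"]
    sd_eps <- vc$sdcor[vc$grp == "Residual"]
    expect_lt(abs(sd_subj - 1), 0.25)
    expect_lt(abs(sd_eps - 1), 0.25)
  })
})

test_that("REML degenerates to OLS when the subject variance hits zero", {
  # seed chosen so the REML subject variance lands on the zero boundary,
  # the regime where mixed-model and OLS fixed effects must coincide
  withr::with_seed(65, {
    d <- sim_longitudinal(n_subj = 120, sd_subj = 0)
    mixed <- suppressMessages(fit_regression(d, "y"))
    vc <- as.data.frame(lme4::VarCorr(attr(mixed, "model")))
    expect_equal(vc$sdcor[vc$grp == "subject_id"], 0)
    ols <- fit_regression(d, "y", random_intercept = NULL)
    expect_equal(mixed$estimate, ols$estimate, tolerance = 1e-6)
  })
})

test_that("exponentiated coefficients preserve the null correspondence", {
  withr::with_seed(63, {
    d <- sim_longitudinal(n_subj = 80, waves = 1, beta5 = 0)
    res <- fit_regression(d, "y", random_intercept = NULL)
    for (i in seq_len(nrow(res))) {
      expect_equal(res$exp_estimate[i], exp(res$estimate[i]))
      contains_one <- res$exp_conf.low[i] <= 1 & res$exp_conf.high[i] >= 1
      contains_zero <- res$conf.low[i] <= 0 & res$conf.high[i] >= 0
      expect_identical(contains_one, contains_zero)
    }
  })
})

test_that("pooled OLS across imputations matches single-fit structure", {
  withr::with_seed(64, {
    d <- sim_longitudinal(n_subj = 100, waves = 1)
    sets <- lapply(1:3, function(i) {
      d2 <- d
      d2$y <- d$y + rnorm(nrow(d), sd = 0.05)  # mimic imputation wobble
      d2
    })
    pooled <- fit_regression_pooled(sets, "y")
    single <- fit_regression(d, "y", random_intercept = NULL)
    expect_identical(pooled$term, single$term)
    expect_equal(pooled$estimate, single$estimate, tolerance = 0.1)
    expect_true(all(pooled$se >= 0))
  })
})

test_that("lipid ratios multiply back to the original lipids", {
  co <- add_lipid_ratios(generate_cohort(cohort_params(n_subjects = 50,
                                                       seed = 5)))
  expect_lt(max(abs(co$tc_hdlc * co$hdlc - co$tc)), 1e-9)
  expect_lt(max(abs(co$tg_hdlc * co$hdlc - co$tg)), 1e-9)
})

test_that("the comparison suite returns one ANOVA row per outcome", {
  withr::with_seed(65, {
    d <- sim_longitudinal(n_subj = 60, waves = 1)
    d$bfp <- d$y
    res <- run_comparison_suite(d, outcomes = "bfp",
                                random_intercept = NULL)
    expect_identical(nrow(res$anova), 1L)
    expect_identical(res$anova$outcome, "bfp")
    expect_true(all(c("sex", "age") %in% res$chisq$variable))
    expect_error(run_comparison_suite(d, outcomes = "nope",
                                      random_intercept = NULL), "nope")
  })
})
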