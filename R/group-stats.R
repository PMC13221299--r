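#' One-way analysis of variance
#'
#' Classical fixed-effects one-way ANOVA: `F = MSB / MSW` with
#' `(k - 1, N - k)` degrees of freedom and the p-value from the F
#' distribution.
#'
#' @param groups List of numeric vectors, one per group (>= 2 groups, each
#'   with >= 2 values).
#' @return One-row tibble: `test`, `statistic`, `df1`, `df2`, `p_value`.
#' @export
oneway_anova <- function(groups) {
  groups <- lapply(groups, function(g) g[!is.na(g)])
  if (length(groups) < 2 || any(lengths(groups) < 2)) {
    stop("need >= 2 groups with >= 2 values each", call. = FALSE)
  }
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  msw <- sum(vapply(groups, function(v) sum((v - mean(v))^2), 0))
  if (msw == 0) {
    stop("zero within-group variance: F statistic undefined", call. = FALSE)
  }
  tab <- stats::anova(lm(y ~ g))
  tibble::tibble(test = "anova_F", statistic = tab$`F value`[1],
                 df1 = tab$Df[1], df2 = tab$Df[2],
                 p_value = tab$`Pr(>F)`[1])
}

#' Pearson chi-square test of independence
#'
#' Pearson statistic `sum((O - E)^2 / E)` on an r x c count table, df
#' `(r - 1)(c - 1)`, without continuity correction.
#'
#' @param tab Matrix (or table) of non-negative counts with positive
#'   margins.
#' @return One-row tibble: `test`, `statistic`, `df`, `p_value`.
#' @export
chi_square <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || sum(tab) <= 0) {
    stop("counts must be non-negative with a positive total", call. = FALSE)
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("zero row/column margin", call. = FALSE)
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  tibble::tibble(test = "chi2", statistic = unname(ct$statistic),
                 df = unname(ct$parameter), p_value = ct$p.value)
}

#' Pearson correlation with t-based p-value
#'
#' @param x,y Numeric vectors (n >= 3, both with positive variance; pairs
#'   with missing values are dropped).
#' @return One-row tibble: `test`, `estimate`, `statistic`, `df`,
#'   `p_value`.
#' @export
pearson_cor <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 3) stop("need n >= 3 complete pairs", call. = FALSE)
  if (var(x) == 0 || var(y) == 0) {
    stop("zero variance in x or y", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  tibble::tibble(test = "pearson_r", estimate = unname(ct$estimate),
                 statistic = unname(ct$statistic),
                 df = unname(ct$parameter), p_value = ct$p.value)
}

# analysis frame shared by the regression paths: cluster as factor with
# cluster 1 the reference, measurement year categorical, sex coded 0/1
# (boys 0, girls 1), age continuous
regression_frame <- function(data, response) {
  needed <- c(response, "cluster", "wave", "sex", "age")
  miss <- setdiff(needed, names(data))
  if (length(miss)) {
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  sex01 <- if (is.numeric(data$sex)) data$sex
           else as.numeric(data$sex == "female")
  out <- data.frame(
    y = data[[response]],
    cluster = stats::relevel(factor(data$cluster), ref = "1"),
    year = factor(data$wave),
    sex01 = sex01,
    age = data$age)
  if ("subject_id" %in% names(data)) out$subject_id <- data$subject_id
  out[stats::complete.cases(out), , drop = FALSE]
}

term_table <- function(est, se, df, conf_level, exponentiate) {
  half <- qt(1 - (1 - conf_level) / 2, df) * se
  out <- tibble::tibble(term = names(est), estimate = unname(est),
                        se = unname(se), df = unname(df),
                        statistic = unname(est / se),
                        p_value = unname(2 * pt(-abs(est / se), df)),
                        conf.low = unname(est - half),
                        conf.high = unname(est + half))
  if (exponentiate) {
    out$exp_estimate <- exp(out$estimate)
    out$exp_conf.low <- exp(out$conf.low)
    out$exp_conf.high <- exp(out$conf.high)
  }
  out
}

#' Cluster-adjusted regression for a health indicator
#'
#' Linear model of the indicator on cluster membership (indicator terms
#' against reference cluster 1), measurement year (categorical), sex
#' (boys 0, girls 1) and age (years).  With `random_intercept` set, a
#' Gaussian random intercept per subject absorbs the repeated annual
#' measurements and the model is fitted by REML ([lme4::lmer()]); without
#' it, ordinary least squares.  Coefficients and Wald confidence-interval
#' endpoints are also reported exponentiated, matching the conventional
#' forest-plot axis.  Degrees of freedom use the residual approximation
#' `n - p`.
#'
#' @param data Tibble with the response plus `cluster`, `wave`, `sex`,
#'   `age` and (for the mixed model) `subject_id`.
#' @param response Response column name.
#' @param random_intercept Grouping column for the random intercept
#'   (`"subject_id"`), or `NULL` for plain OLS.
#' @param conf_level Confidence level for the intervals.
#' @param exponentiate Add `exp()`-transformed columns?
#' @return Tibble of per-term results; the fitted model is attached as
#'   `attr(, "model")`.
#' @export
fit_regression <- function(data, response, random_intercept = "subject_id",
                           conf_level = 0.95, exponentiate = TRUE) {
  df <- regression_frame(data, response)
  # drop degenerate covariates (single-level factors, constant columns)
  rhs <- c("cluster", "year", "sex01", "age")
  ok <- vapply(rhs, function(v) {
    x <- df[[v]]
    if (is.factor(x)) nlevels(droplevels(x)) > 1 else var(x) > 0
  }, TRUE)
  if (!ok[["cluster"]]) stop("cluster has a single level", call. = FALSE)
  rhs <- rhs[ok]
  use_re <- !is.null(random_intercept) && "subject_id" %in% names(df) &&
    any(duplicated(df$subject_id))
  if (use_re) {
    fml <- stats::reformulate(c(rhs, "(1 | subject_id)"), response = "y")
    fit <- lme4::lmer(fml, data = df, REML = TRUE)
    est <- lme4::fixef(fit)
    se <- sqrt(diag(as.matrix(stats::vcov(fit))))
    resid_df <- nrow(df) - length(est)
  } else {
    fit <- lm(stats::reformulate(rhs, response = "y"), data = df)
    cf <- coef(fit)
    if (anyNA(cf)) {
      stop("rank-deficient design; aliased term(s): ",
           paste(names(cf)[is.na(cf)], collapse = ", "), call. = FALSE)
    }
    est <- cf
    se <- sqrt(diag(stats::vcov(fit)))
    resid_df <- fit$df.residual
  }
  out <- term_table(est, se, rep(resid_df, length(est)), conf_level,
                    exponentiate)
  attr(out, "model") <- fit
  out
}

#' Pooled regression across multiply imputed datasets
#'
#' Fits the cluster-adjusted model by OLS on each completed dataset (no
#' random intercept — the multiple-imputation sensitivity route) and pools
#' each term with Rubin's rules before exponentiating.
#'
#' @param datasets List of completed data frames (all with the analysis
#'   columns), e.g. the imputations of [mice_pmm()] joined back to the
#'   design columns.
#' @inheritParams fit_regression
#' @return Tibble of pooled per-term results with `exp_` columns.
#' @export
fit_regression_pooled <- function(datasets, response, conf_level = 0.95,
                                  exponentiate = TRUE) {
  stopifnot(is.list(datasets), length(datasets) >= 2)
  fits <- lapply(datasets, function(d) {
    fit_regression(d, response, random_intercept = NULL,
                   conf_level = conf_level, exponentiate = FALSE)
  })
  terms <- fits[[1]]$term
  dfcom <- fits[[1]]$df[1]
  rows <- lapply(seq_along(terms), function(i) {
    est <- vapply(fits, function(f) f$estimate[i], 0)
    v <- vapply(fits, function(f) f$se[i]^2, 0)
    pooled <- pool_rubin(est, v, dfcom = dfcom, conf_level = conf_level)
    out <- tibble::tibble(term = terms[i], estimate = pooled$estimate,
                          se = pooled$se, df = pooled$df,
                          statistic = pooled$estimate / pooled$se,
                          p_value = 2 * pt(-abs(pooled$estimate / pooled$se),
                                           pooled$df),
                          conf.low = pooled$conf.low,
                          conf.high = pooled$conf.high)
    if (exponentiate) {
      out$exp_estimate <- exp(out$estimate)
      out$exp_conf.low <- exp(out$conf.low)
      out$exp_conf.high <- exp(out$conf.high)
    }
    out
  })
  dplyr::bind_rows(rows)
}

#' Lipid-ratio columns
#'
#' Adds `tc_hdlc = tc / hdlc` and `tg_hdlc = tg / hdlc`.
#'
#' @param cohort Tibble with `tc`, `tg`, `hdlc`.
#' @return The cohort with the two ratio columns.
#' @export
add_lipid_ratios <- function(cohort) {
  dplyr::mutate(cohort, tc_hdlc = .data$tc / .data$hdlc,
                tg_hdlc = .data$tg / .data$hdlc)
}

#' Between-cluster comparison suite
#'
#' For each numeric health indicator: one-way ANOVA across the clusters
#' and the cluster-adjusted regression.  For the categorical/demographic
#' variables (sex, measurement year, integer age): chi-square tests of the
#' cluster x category contingency table.
#'
#' @param cohort Clustered (and imputed) cohort with a `cluster` column.
#' @param outcomes Numeric indicator columns to compare.
#' @param random_intercept Passed to [fit_regression()].
#' @return List with tibbles `anova`, `chisq` and `regression`.
#' @export
run_comparison_suite <- function(cohort,
                                 outcomes = c("bfp", "ac", "tc_hdlc",
                                              "tg_hdlc", "steps_per_day",
                                              "activity_min", "sleep_min"),
                                 random_intercept = "subject_id") {
  if (!"cluster" %in% names(cohort)) {
    stop("cohort lacks a `cluster` column", call. = FALSE)
  }
  if (any(c("tc_hdlc", "tg_hdlc") %in% outcomes) &&
      !all(c("tc_hdlc", "tg_hdlc") %in% names(cohort)) &&
      all(c("tc", "tg", "hdlc") %in% names(cohort))) {
    cohort <- add_lipid_ratios(cohort)
  }
  miss <- setdiff(outcomes, names(cohort))
  if (length(miss)) {
    stop("missing outcome column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  anova_rows <- lapply(outcomes, function(oc) {
    res <- oneway_anova(split(cohort[[oc]], cohort$cluster))
    tibble::tibble(outcome = oc, res)
  })
  reg_rows <- lapply(outcomes, function(oc) {
    res <- fit_regression(cohort, oc, random_intercept = random_intercept)
    tibble::tibble(outcome = oc, res)
  })
  chi_vars <- intersect(c("sex", "wave"), names(cohort))
  chi_rows <- lapply(chi_vars, function(v) {
    tab <- table(cohort$cluster, cohort[[v]])
    tibble::tibble(variable = v, chi_square(tab))
  })
  if ("age" %in% names(cohort)) {
    tab <- table(cohort$cluster, floor(cohort$age))
    chi_rows <- c(chi_rows, list(tibble::tibble(variable = "age",
                                                chi_square(tab))))
  }
  list(anova = dplyr::bind_rows(anova_rows),
       chisq = dplyr::bind_rows(chi_rows),
       regression = dplyr::bind_rows(reg_rows))
}
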