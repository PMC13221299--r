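#' k-nearest-neighbour imputation
#'
#' Distance between two rows is the Euclidean distance over the features
#' observed in *both* rows, with each feature scaled by its column SD
#' (computed over observed values) and the sum inflated by the inverse
#' proportion of mutually observed features:
#' `d(a, b) = sqrt(p / |M| * sum_{j in M} ((a_j - b_j) / s_j)^2)`,
#' where `p` is the number of features and `M` the mutually observed set.
#' Each missing cell is filled with the unweighted mean of the `k` nearest
#' rows having that feature observed; when fewer than `k` such donors
#' exist, all available donors are used.  Distance ties are broken by row
#' order.
#'
#' @param X Numeric data frame or matrix with `NA`s.
#' @param k Number of donor neighbours.
#' @param scale `"sd"` (default) or `"none"` (unit scaling).
#' @return A completed tibble; observed cells are untouched.
#' @export
knn_impute <- function(X, k = 5, scale = c("sd", "none")) {
  scale <- match.arg(scale)
  Xm <- as.matrix(as.data.frame(X))
  storage.mode(Xm) <- "double"
  n <- nrow(Xm)
  p <- ncol(Xm)
  fully_missing <- colSums(!is.na(Xm)) == 0
  if (any(fully_missing)) {
    stop("column(s) fully missing: ",
         paste(colnames(Xm)[fully_missing], collapse = ", "), call. = FALSE)
  }
  if (any(rowSums(!is.na(Xm)) == 0)) {
    stop("row(s) with no observed feature", call. = FALSE)
  }
  s <- if (scale == "sd") apply(Xm, 2, sd, na.rm = TRUE) else rep(1, p)
  s[!is.finite(s) | s == 0] <- 1
  Xs <- sweep(Xm, 2, s, "/")

  out <- Xm
  miss_rows <- which(rowSums(is.na(Xm)) > 0)
  for (i in miss_rows) {
    diffs <- sweep(Xs, 2, Xs[i, ], "-")
    mutual <- !is.na(Xs) & matrix(!is.na(Xs[i, ]), n, p, byrow = TRUE)
    m_count <- rowSums(mutual)
    ss <- rowSums((diffs^2) * mutual, na.rm = TRUE)
    d <- sqrt(ifelse(m_count > 0, p / m_count * ss, Inf))
    d[i] <- Inf
    for (j in which(is.na(Xm[i, ]))) {
      donors <- which(!is.na(Xm[, j]) & seq_len(n) != i)
      ord <- donors[order(d[donors], donors)]
      fin <- ord[is.finite(d[ord])]
      use <- if (length(fin)) head(fin, k) else head(ord, k)
      out[i, j] <- mean(Xm[use, j])
    }
  }
  tibble::as_tibble(as.data.frame(out))
}

#' Multiple imputation by chained equations with predictive mean matching
#'
#' Chained-equation multiple imputation: missing cells are initialised by
#' random draws from each column's observed values, then the columns with
#' missing data are visited in ascending order of missing count.  Each
#' target column is regressed on all other columns (ordinary least squares
#' over the originally observed rows), regression noise and coefficients
#' are drawn from their Bayesian posterior (scaled inverse-chi-squared
#' sigma^2, Gaussian coefficients), and each missing cell is replaced by
#' the observed value of a donor sampled uniformly from the `n_donors`
#' observed rows whose predicted mean (under the posterior-mean
#' coefficients) is closest to the cell's prediction (under the drawn
#' coefficients).  The cycle runs `n_iter` times; the whole process is
#' repeated `m` times under split seeds.
#'
#' Every imputed value is an observed value of its own column, so imputed
#' data can never leave the observed support.
#'
#' @param X Numeric data frame with `NA`s (non-numeric columns are not
#'   allowed).
#' @param m Number of imputed datasets.
#' @param n_iter Chained-equation cycles per dataset.
#' @param n_donors Donor-pool size for the matching step.
#' @param seed Master seed (default 1234).
#' @return An `imputation_set`: list with `imputations` (list of `m`
#'   completed tibbles), plus the settings.
#' @export
mice_pmm <- function(X, m = 20, n_iter = 50, n_donors = 5, seed = 1234) {
  Xd <- as.data.frame(X)
  if (!all(vapply(Xd, is.numeric, TRUE))) {
    stop("all columns must be numeric", call. = FALSE)
  }
  Xm <- as.matrix(Xd)
  n <- nrow(Xm)
  na_mask <- is.na(Xm)
  n_obs <- colSums(!na_mask)
  short <- n_obs < n_donors & colSums(na_mask) > 0
  if (any(short)) {
    stop("insufficient observed donors in column(s): ",
         paste(colnames(Xm)[short], collapse = ", "), call. = FALSE)
  }
  visit <- order(colSums(na_mask))
  visit <- visit[colSums(na_mask)[visit] > 0]

  one_imputation <- function(imp_seed) {
    withr::with_seed(imp_seed, {
      cur <- Xm
      for (j in seq_len(ncol(cur))) {
        mis <- which(na_mask[, j])
        if (length(mis)) {
          cur[mis, j] <- sample(cur[!na_mask[, j], j], length(mis),
                                replace = TRUE)
        }
      }
      for (iter in seq_len(n_iter)) {
        for (j in visit) {
          obs <- which(!na_mask[, j])
          mis <- which(na_mask[, j])
          D <- cbind(1, cur[, -j, drop = FALSE])
          qrD <- qr(D[obs, , drop = FALSE])
          keep_cols <- qrD$pivot[seq_len(qrD$rank)]
          Do <- D[obs, keep_cols, drop = FALSE]
          y <- cur[obs, j]
          fit <- lm.fit(Do, y)
          beta_hat <- fit$coefficients
          df <- length(obs) - qrD$rank
          rss <- sum(fit$residuals^2)
          sigma2 <- if (df > 0) rss / stats::rchisq(1, df) else rss
          XtXinv <- chol2inv(qr.R(qr(Do)))
          beta_draw <- beta_hat +
            drop(t(chol(sigma2 * (XtXinv + diag(1e-10, nrow(XtXinv))))) %*%
                   rnorm(length(beta_hat)))
          pred_obs <- drop(Do %*% beta_hat)
          pred_mis <- drop(D[mis, keep_cols, drop = FALSE] %*% beta_draw)
          for (idx in seq_along(mis)) {
            gaps <- abs(pred_obs - pred_mis[idx])
            pool <- obs[order(gaps, seq_along(gaps))][seq_len(n_donors)]
            cur[mis[idx], j] <- cur[pool[sample.int(n_donors, 1)], j]
          }
        }
      }
      tibble::as_tibble(as.data.frame(cur))
    })
  }

  imps <- lapply(seq_len(m), function(i) {
    one_imputation(derive_seed(seed, paste0("mice/", i)))
  })
  structure(list(imputations = imps, method = "pmm", m = m,
                 n_iter = n_iter, n_donors = n_donors, seed = seed,
                 na_mask = na_mask),
            class = "imputation_set")
}

#' @export
print.imputation_set <- function(x, ...) {
  cat(sprintf("<imputation_set> m = %d (%s), %d iterations, seed %s\n",
              x$m, x$method, x$n_iter, format(x$seed)))
  invisible(x)
}

#' Pool estimates across multiply imputed datasets (Rubin's rules)
#'
#' Pooled estimate = mean of the per-imputation estimates; total variance =
#' within-imputation variance plus `(1 + 1/m)` times the between-imputation
#' variance.  The confidence interval uses a t reference with
#' Barnard-Rubin-adjusted degrees of freedom when the complete-data df is
#' finite.
#'
#' @param estimates Numeric vector of per-imputation estimates (m >= 2).
#' @param variances Matching squared standard errors.
#' @param dfcom Complete-data residual degrees of freedom (`Inf` for the
#'   large-sample version).
#' @param conf_level Confidence level.
#' @return A one-row tibble: `estimate`, `within`, `between`, `variance`,
#'   `se`, `df`, `conf.low`, `conf.high`.
#' @export
pool_rubin <- function(estimates, variances, dfcom = Inf,
                       conf_level = 0.95) {
  m <- length(estimates)
  if (m < 2 || length(variances) != m) {
    stop("need m >= 2 estimates with matching variances", call. = FALSE)
  }
  qbar <- mean(estimates)
  ubar <- mean(variances)
  b <- var(estimates)
  t_var <- ubar + (1 + 1 / m) * b
  lambda <- if (t_var > 0) (1 + 1 / m) * b / t_var else 0
  df <- if (lambda > 0) (m - 1) / lambda^2 else Inf
  if (is.finite(dfcom)) {
    df_obs <- (dfcom + 1) / (dfcom + 3) * dfcom * (1 - lambda)
    df <- 1 / (1 / df + 1 / df_obs)
  }
  half <- qt(1 - (1 - conf_level) / 2, df) * sqrt(t_var)
  tibble::tibble(estimate = qbar, within = ubar, between = b,
                 variance = t_var, se = sqrt(t_var), df = df,
                 conf.low = qbar - half, conf.high = qbar + half)
}

#' Missing-value summary for a cohort table
#'
#' Counts and percentages of missing values per measurement.  The lipid
#' panel is reported as one measurement (a missed blood draw nulls TC, TG
#' and HDLC together), using the TC column.
#'
#' @param cohort Cohort tibble.
#' @param fields Named list mapping measurement names to the column
#'   counted.
#' @return Tibble with `field`, `n_missing`, `n_total`, `pct_missing`.
#' @export
summarize_missingness <- function(cohort,
                                  fields = list(ac = "ac", lipids = "tc",
                                                steps = "steps_per_day",
                                                activity = "activity_min",
                                                sleep = "sleep_min")) {
  rows <- lapply(names(fields), function(nm) {
    col <- fields[[nm]]
    if (!col %in% names(cohort)) {
      stop("no column '", col, "' for field '", nm, "'", call. = FALSE)
    }
    tibble::tibble(field = nm, n_missing = sum(is.na(cohort[[col]])),
                   n_total = nrow(cohort),
                   pct_missing = 100 * sum(is.na(cohort[[col]])) /
                     nrow(cohort))
  })
  dplyr::bind_rows(rows)
}

#' Complete-case filtering
#'
#' Drops rows with any missing value among the named columns.
#'
#' @param X Data frame.
#' @param columns Columns to require complete (default all).
#' @return The filtered tibble; the number of dropped rows is messaged.
#' @export
complete_cases <- function(X, columns = names(X)) {
  stopifnot(all(columns %in% names(X)))
  ok <- stats::complete.cases(X[, columns, drop = FALSE])
  if (any(!ok)) {
    message(sum(!ok), " incomplete row(s) removed")
  }
  tibble::as_tibble(X[ok, , drop = FALSE])
}
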