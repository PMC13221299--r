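#' Body-composition index from a component mass and height
#'
#' A body-composition index (BCI) is a component mass divided by the square
#' of height, in kg/m^2 — the same construction as BMI, applied to fat,
#' lean, muscle, bone or total-body-water mass.
#'
#' @param mass Component mass in kg (>= 0).
#' @param height Height in cm (> 0).
#' @return Index in kg/m^2.
#' @export
#' @examples
#' compute_bci(20, 125)  # 12.8
compute_bci <- function(mass, height) {
  if (any(!is.finite(height)) || any(height <= 0)) {
    stop("`height` must be positive (cm)", call. = FALSE)
  }
  if (any(mass < 0, na.rm = TRUE)) {
    stop("`mass` must be non-negative (kg)", call. = FALSE)
  }
  mass / (height / 100)^2
}

#' Add BCI columns to a cohort table
#'
#' Computes `bmi`, `fmi`, `lmi`, `mmi`, `bni` and `twi` from the component
#' masses and height.
#'
#' @param cohort Cohort tibble with `height`, `weight` and the component
#'   mass columns.
#' @return The cohort with six index columns appended.
#' @export
add_bci <- function(cohort) {
  dplyr::mutate(
    cohort,
    bmi = compute_bci(.data$weight, .data$height),
    fmi = compute_bci(.data$fat_mass, .data$height),
    lmi = compute_bci(.data$lean_mass, .data$height),
    mmi = compute_bci(.data$muscle_mass, .data$height),
    bni = compute_bci(.data$bone_mass, .data$height),
    twi = compute_bci(.data$water_mass, .data$height))
}

#' Per-age, per-sex bin statistics
#'
#' Groups observations by sex and integer age (floor) and returns the count,
#' mean and sample SD (n-1 denominator) of each index in each bin.  Bins
#' with fewer than two observations cannot contribute an SD and are dropped
#' with a warning.
#'
#' @param data Tibble with `sex`, `age` and the index columns.
#' @param indices Character vector of index column names.
#' @return Tibble with columns `sex`, `age_int`, `index`, `n`, `mean`, `sd`.
#' @export
bin_stats <- function(data,
                      indices = c("bmi", "fmi", "lmi", "mmi", "bni", "twi")) {
  missing_cols <- setdiff(c("sex", "age", indices), names(data))
  if (length(missing_cols)) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  long <- tidyr::pivot_longer(
    dplyr::mutate(data[, c("sex", "age", indices)],
                  age_int = as.integer(floor(.data$age))),
    cols = dplyr::all_of(indices), names_to = "index", values_to = "value")
  out <- dplyr::summarise(
    dplyr::group_by(long, .data$sex, .data$age_int, .data$index),
    n = sum(is.finite(.data$value)),
    mean = base::mean(.data$value[is.finite(.data$value)]),
    sd = stats::sd(.data$value[is.finite(.data$value)]),
    .groups = "drop")
  small <- out$n < 2
  if (any(small)) {
    bad <- unique(sprintf("%s/age %d", out$sex[small], out$age_int[small]))
    warning("dropping bins with n < 2: ", paste(bad, collapse = "; "),
            call. = FALSE)
    out <- out[!small, , drop = FALSE]
  }
  out
}

new_bci_reference <- function(coefficients, age_domain, sd_floor = 1e-6,
                              degree = 3L) {
  structure(list(coefficients = coefficients,
                 age_domain = as.numeric(age_domain),
                 sd_floor = sd_floor, degree = as.integer(degree),
                 version = "1.0"),
            class = "bci_reference")
}

#' @export
print.bci_reference <- function(x, ...) {
  cat(sprintf("<bci_reference> %d sex x index curve sets, age domain [%g, %g]\n",
              nrow(x$coefficients) / 3, x$age_domain[1], x$age_domain[2]))
  invisible(x)
}

#' Fit reference-value curves to bin statistics
#'
#' For each sex x index, three scores are formed from the per-integer-age
#' bins — the mean and the mean +/- 1 SD — and each score series is fitted
#' with a least-squares cubic polynomial in integer age.  The three
#' coefficient vectors (ascending powers) plus residual sums of squares are
#' stored.  At evaluation time the SD at an age is recovered as
#' `(upper - lower) / 2`.
#'
#' @param bins Output of [bin_stats()].
#' @param degree Polynomial degree (3 = cubic).
#' @param sd_floor Minimum SD used when standardizing, in index units.
#' @return A `bci_reference` object.
#' @export
fit_reference <- function(bins, degree = 3, sd_floor = 1e-6) {
  stopifnot(is.data.frame(bins), degree >= 1, degree <= 3)
  groups <- split(bins, list(bins$sex, bins$index), drop = TRUE)
  rows <- lapply(names(groups), function(g) {
    b <- groups[[g]]
    ages <- b$age_int
    if (length(unique(ages)) < degree + 1) {
      stop(sprintf("fewer than %d distinct integer ages for %s/%s",
                   degree + 1, b$sex[1], b$index[1]), call. = FALSE)
    }
    scores <- list(mean = b$mean, upper = b$mean + b$sd,
                   lower = b$mean - b$sd)
    out <- lapply(names(scores), function(curve) {
      fit <- lm(scores[[curve]] ~ poly(ages, degree, raw = TRUE))
      cf <- unname(coef(fit))
      cf[is.na(cf)] <- 0
      cf <- c(cf, rep(0, 4))[1:4]  # pad when degree < 3
      tibble::tibble(sex = b$sex[1], index = b$index[1], curve = curve,
                     c0 = cf[1], c1 = cf[2], c2 = cf[3], c3 = cf[4],
                     rss = sum(fit$residuals^2))
    })
    dplyr::bind_rows(out)
  })
  coefs <- dplyr::bind_rows(rows)
  # a bin at integer age a covers observed ages [a, a + 0.9]
  new_bci_reference(coefs,
                    age_domain = c(min(bins$age_int),
                                   max(bins$age_int) + 0.9),
                    sd_floor = sd_floor, degree = degree)
}

ref_coefs <- function(model, sex, index, curve) {
  cf <- model$coefficients
  row <- cf[cf$sex == sex & cf$index == index & cf$curve == curve, ]
  if (nrow(row) != 1) {
    stop(sprintf("no reference curve for sex='%s', index='%s'", sex, index),
         call. = FALSE)
  }
  as.numeric(row[1, c("c0", "c1", "c2", "c3")])
}

#' Evaluate a reference model at an age
#'
#' Ages are first rounded to one decimal place, matching the reference-table
#' resolution.  The mean is the mean-curve polynomial; the SD is
#' `(upper(age) - lower(age)) / 2`, floored at the model's `sd_floor`.  By
#' default ages outside the fitted age domain are an error, because cubic
#' tails extrapolate poorly; `clamp = TRUE` evaluates at the nearest domain
#' boundary instead.
#'
#' @param model A `bci_reference`.
#' @param sex `"male"` or `"female"`.
#' @param index Index name, e.g. `"fmi"`.
#' @param age Age(s) in years.
#' @param clamp Clamp out-of-domain ages to the boundary?
#' @return A list with numeric vectors `mean` and `sd`.
#' @export
evaluate_reference <- function(model, sex, index, age, clamp = FALSE) {
  stopifnot(inherits(model, "bci_reference"))
  age <- round(age, 1)
  lo <- model$age_domain[1]
  hi <- model$age_domain[2]
  if (clamp) {
    age <- pmin(pmax(age, lo), hi)
  } else if (any(age < lo | age > hi, na.rm = TRUE)) {
    stop(sprintf("age outside reference domain [%g, %g] (use clamp = TRUE)",
                 lo, hi), call. = FALSE)
  }
  mean_v <- poly_eval(ref_coefs(model, sex, index, "mean"), age)
  upper <- poly_eval(ref_coefs(model, sex, index, "upper"), age)
  lower <- poly_eval(ref_coefs(model, sex, index, "lower"), age)
  list(mean = mean_v, sd = pmax((upper - lower) / 2, model$sd_floor))
}

#' Standardize a value against a reference model
#'
#' `z = (value - mean(age, sex)) / sd(age, sex)`.
#'
#' @inheritParams evaluate_reference
#' @param value Observed index value(s), kg/m^2.
#' @return Numeric z-score(s).
#' @export
zscore <- function(model, value, sex, index, age, clamp = FALSE) {
  ref <- evaluate_reference(model, sex, index, age, clamp = clamp)
  (value - ref$mean) / ref$sd
}

#' Z-score an entire cohort
#'
#' Adds a `z_<index>` column for each requested index, standardized per row
#' against the subject's sex and age.
#'
#' @param model A `bci_reference`.
#' @param cohort Cohort tibble containing `sex`, `age` and the index
#'   columns (see [add_bci()]).
#' @param indices Index columns to standardize.
#' @param clamp Passed to [evaluate_reference()].
#' @return The cohort with z-score columns appended.
#' @export
cohort_zscores <- function(model, cohort,
                           indices = c("bmi", "fmi", "lmi", "mmi", "bni",
                                       "twi"),
                           clamp = FALSE) {
  out <- cohort
  for (idx in indices) {
    z <- rep(NA_real_, nrow(cohort))
    for (sx in unique(cohort$sex)) {
      rows <- which(cohort$sex == sx)
      z[rows] <- zscore(model, cohort[[idx]][rows], sx, idx,
                        cohort$age[rows], clamp = clamp)
    }
    out[[paste0("z_", idx)]] <- z
  }
  out
}

#' Export a reference model as a mean/SD grid
#'
#' One row per sex x index x age on a 0.1-year grid over the age domain —
#' the layout of a printable reference table.
#'
#' @param model A `bci_reference`.
#' @param step Age grid step in years.
#' @return Tibble with `sex`, `index`, `age`, `mean`, `sd`.
#' @export
export_reference_table <- function(model, step = 0.1) {
  stopifnot(inherits(model, "bci_reference"))
  ages <- round(seq(model$age_domain[1], model$age_domain[2], by = step), 1)
  keys <- unique(model$coefficients[, c("sex", "index")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    ref <- evaluate_reference(model, keys$sex[i], keys$index[i], ages)
    tibble::tibble(sex = keys$sex[i], index = keys$index[i], age = ages,
                   mean = ref$mean, sd = ref$sd)
  })
  dplyr::bind_rows(rows)
}

#' Serialize / restore a reference model
#'
#' JSON round-trip of the full model (coefficients in ascending powers, age
#' domain, SD floor, schema version) at full double precision, so that a
#' restored model reproduces byte-identical z-scores.
#'
#' @param model A `bci_reference`.
#' @param path Output path (`.json`).
#' @return `read_reference()` returns the restored `bci_reference`.
#' @export
write_reference <- function(model, path) {
  stopifnot(inherits(model, "bci_reference"))
  cf <- model$coefficients
  for (col in c("c0", "c1", "c2", "c3", "rss")) {
    # %.17g round-trips IEEE doubles exactly through text
    cf[[col]] <- sprintf("%.17g", cf[[col]])
  }
  payload <- list(version = model$version, degree = model$degree,
                  age_domain = model$age_domain, sd_floor = model$sd_floor,
                  coefficients = cf)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_reference
#' @export
read_reference <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  cf <- tibble::as_tibble(payload$coefficients)
  for (col in c("c0", "c1", "c2", "c3", "rss")) {
    cf[[col]] <- as.numeric(cf[[col]])
  }
  new_bci_reference(cf, age_domain = payload$age_domain,
                    sd_floor = payload$sd_floor,
                    degree = payload$degree)
}

#' Fit a reference model straight from a cohort
#'
#' Convenience wrapper: computes indices if absent, bins by sex and integer
#' age, and fits the cubic reference curves.
#'
#' @param cohort Cohort tibble.
#' @param indices Index columns.
#' @param first_per_child Restrict to each child's first observation before
#'   fitting (default pools all subject-wave observations).
#' @inheritParams fit_reference
#' @return A `bci_reference`.
#' @export
build_reference <- function(cohort,
                            indices = c("bmi", "fmi", "lmi", "mmi", "bni",
                                        "twi"),
                            degree = 3, sd_floor = 1e-6,
                            first_per_child = FALSE) {
  if (!all(indices %in% names(cohort))) cohort <- add_bci(cohort)
  if (first_per_child) {
    cohort <- dplyr::slice_min(dplyr::group_by(cohort, .data$subject_id),
                               .data$wave, n = 1, with_ties = FALSE)
    cohort <- dplyr::ungroup(cohort)
  }
  fit_reference(bin_stats(cohort, indices), degree = degree,
                sd_floor = sd_floor)
}
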