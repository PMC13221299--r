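#' Default parameters for the synthetic cohort generator
#'
#' Builds the parameter list consumed by [generate_cohort()].  The defaults
#' emulate the structure of a three-wave school cohort: ~353 children aged
#' 7-14 measured annually, per-wave participation probabilities matching the
#' published per-year dataset counts (336, 318, 263 of 353), bioimpedance
#' mass identities (fat + lean = weight, muscle + bone = lean, water < lean),
#' near-collinear lean/muscle/water indices, and missing-data rates at the
#' published per-measurement frequencies.
#'
#' Component means and SDs are cubic polynomials in age (ascending powers,
#' kg/m^2), one set per sex.  Subject-level variation is expressed in z-space
#' relative to these generating curves: either a latent-factor model (a
#' shared "body size" factor inducing the fat-lean correlation) or, when
#' `cluster_centroids` is supplied, a five-component mixture in
#' (FMI, MMI, BNI) z-space with the given mixing weights and within-cluster
#' SD.
#'
#' @param n_subjects Number of children enrolled.
#' @param waves Number of annual measurement waves.
#' @param participation Per-wave participation probabilities (length `waves`).
#' @param age_range Baseline (wave-1) age range in years; ages advance by
#'   exactly 1.0 per wave.
#' @param curves Named list `curves[[sex]][[index]]$mean` / `$sd`, cubic
#'   coefficient vectors (length 4, ascending powers) for indices
#'   `"fmi"`, `"mmi"`, `"bni"` and `"height"` (height in cm).
#' @param fat_loading,lean_loading Latent-factor loadings in (0, 1); the
#'   implied fat-lean z correlation is `fat_loading * lean_loading`.
#' @param bone_muscle_loading Correlation loading of the bone z-score on the
#'   muscle z-score; values near 1 make LMI, MMI and TWI nearly collinear.
#' @param water_fraction Mean total-body-water share of lean mass.
#' @param water_fraction_sd SD of the per-observation water share.
#' @param height_sd Residual SD of height (cm) around its age curve.
#' @param cluster_centroids Optional `k x 3` matrix of planted centroids in
#'   (FMI, MMI, BNI) z-space; rownames are cluster labels.
#' @param cluster_weights Mixing weights (sum to 1) for the centroids.
#' @param within_sd Within-cluster SD in z units.
#' @param wave_jitter_sd SD of the per-wave jitter added to a subject's
#'   z-vector (year-to-year biological fluctuation).
#' @param missing_rates Named list of missingness probabilities for the
#'   nullable fields: `ac`, `lipids` (TC/TG/HDLC jointly), `steps`,
#'   `activity`, `sleep`.
#' @param seed Master seed; every draw uses a stream derived from it.
#' @return A list of class `"cohort_params"`.
#' @export
cohort_params <- function(n_subjects = 353,
                          waves = 3,
                          participation = c(336, 318, 263) / 353,
                          age_range = c(7.0, 11.9),
                          curves = default_bci_curves(),
                          fat_loading = 0.85,
                          lean_loading = 0.88,
                          bone_muscle_loading = 0.95,
                          water_fraction = 0.73,
                          water_fraction_sd = 0.004,
                          height_sd = 5.0,
                          cluster_centroids = NULL,
                          cluster_weights = NULL,
                          within_sd = 0.3,
                          wave_jitter_sd = 0.1,
                          missing_rates = default_missing_rates(),
                          seed = 1L) {
  stopifnot(n_subjects >= 0, waves >= 1, length(participation) == waves)
  assert_prob(participation, "participation")
  if (!is.numeric(age_range) || length(age_range) != 2 ||
      age_range[1] >= age_range[2] || age_range[1] < 7 ||
      age_range[2] + (waves - 1) > 14) {
    stop("invalid `age_range`: baseline ages must lie in [7, 14 - waves + 1]",
         call. = FALSE)
  }
  for (sx in c("male", "female")) {
    for (idx in c("fmi", "mmi", "bni", "height")) {
      crv <- curves[[sx]][[idx]]
      if (is.null(crv$mean) || is.null(crv$sd)) {
        stop(sprintf("curves$%s$%s must provide $mean and $sd", sx, idx),
             call. = FALSE)
      }
      if (any(poly_eval(crv$sd, seq(age_range[1], age_range[2] + waves - 1,
                                    by = 0.5)) <= 0)) {
        stop(sprintf("SD curve for %s/%s non-positive over the age range",
                     sx, idx), call. = FALSE)
      }
    }
  }
  if (!is.null(cluster_centroids)) {
    cluster_centroids <- as.matrix(cluster_centroids)
    stopifnot(ncol(cluster_centroids) == 3)
    if (is.null(cluster_weights)) {
      cluster_weights <- rep(1 / nrow(cluster_centroids),
                             nrow(cluster_centroids))
    }
    stopifnot(length(cluster_weights) == nrow(cluster_centroids))
    if (abs(sum(cluster_weights) - 1) > 1e-8) {
      stop("`cluster_weights` must sum to 1", call. = FALSE)
    }
  }
  if (within_sd < 0 || wave_jitter_sd < 0 || height_sd < 0) {
    stop("noise SDs must be non-negative", call. = FALSE)
  }
  for (nm in names(missing_rates)) assert_prob(missing_rates[[nm]], nm)
  structure(
    list(n_subjects = as.integer(n_subjects), waves = as.integer(waves),
         participation = participation, age_range = age_range,
         curves = curves, fat_loading = fat_loading,
         lean_loading = lean_loading,
         bone_muscle_loading = bone_muscle_loading,
         water_fraction = water_fraction,
         water_fraction_sd = water_fraction_sd, height_sd = height_sd,
         cluster_centroids = cluster_centroids,
         cluster_weights = cluster_weights, within_sd = within_sd,
         wave_jitter_sd = wave_jitter_sd, missing_rates = missing_rates,
         seed = as.integer(seed)),
    class = "cohort_params"
  )
}

#' Default generating curves for body-composition indices
#'
#' Cubic coefficient vectors (ascending powers of age in years) for the mean
#' and SD of FMI, MMI and BNI (kg/m^2) and of height (cm), per sex.  The
#' shapes are mild age trends plausible for Japanese school children: FMI
#' dips then rises through the adiposity rebound, MMI and BNI rise steadily,
#' girls carry slightly more fat and slightly less muscle.
#'
#' @return Named list `list(male = ..., female = ...)`.
#' @export
default_bci_curves <- function() {
  base <- list(
    fmi    = list(mean = c(4.4, -0.25, 0.02, 0), sd = c(0.04, 0.08, 0, 0)),
    mmi    = list(mean = c(9.0, 0.30, -0.006, 0), sd = c(0.61, 0.02, 0, 0)),
    bni    = list(mean = c(0.55, 0.04, 0, 0), sd = c(0.035, 0.005, 0, 0)),
    height = list(mean = c(81, 5.9, 0, 0), sd = c(5.5, 0, 0, 0))
  )
  female <- base
  female$fmi$mean[1] <- female$fmi$mean[1] + 0.4
  female$mmi$mean[1] <- female$mmi$mean[1] - 0.3
  list(male = base, female = female)
}

#' Default missingness rates for the nullable cohort fields
#'
#' Per-measurement missingness probabilities matching the published counts
#' out of 917 observations: abdominal circumference 3 (0.33%), lipid panel
#' 110 (12.00%), steps 86 (9.38%), activity duration 134 (14.61%), sleep
#' duration 183 (19.96%).
#'
#' @return Named list of rates.
#' @export
default_missing_rates <- function() {
  list(ac = 3 / 917, lipids = 110 / 917, steps = 86 / 917,
       activity = 134 / 917, sleep = 183 / 917)
}

#' Default planted cluster centroids
#'
#' Five centroids in (FMI, MMI, BNI) z-space mirroring the qualitative
#' subpopulation structure reported for school children: one low-everything
#' group, two near-average groups, one uniformly-high group, and one
#' high-fat / average-muscle group, with the low cluster most common.
#'
#' @return A 5 x 3 matrix with a `"weights"` attribute.
#' @export
default_cluster_centroids <- function() {
  m <- rbind(
    c(-1.10, -1.10, -1.10),
    c(-0.45, -0.45, -0.45),
    c( 0.35,  0.35,  0.35),
    c( 1.40,  1.30,  1.30),
    c( 1.90,  0.15,  0.10)
  )
  dimnames(m) <- list(paste0("c", 1:5), c("fmi", "mmi", "bni"))
  attr(m, "weights") <- c(0.30, 0.24, 0.20, 0.14, 0.12)
  m
}

# draw per-subject z-vectors (fmi, mmi, bni) + optional true labels
draw_subject_z <- function(params, n) {
  if (!is.null(params$cluster_centroids)) {
    k <- nrow(params$cluster_centroids)
    lab <- sample.int(k, n, replace = TRUE, prob = params$cluster_weights)
    z <- params$cluster_centroids[lab, , drop = FALSE] +
      matrix(rnorm(3 * n, sd = params$within_sd), ncol = 3)
    dimnames(z) <- list(NULL, c("fmi", "mmi", "bni"))
    list(z = z, labels = lab)
  } else {
    g <- rnorm(n)
    zf <- params$fat_loading * g +
      sqrt(1 - params$fat_loading^2) * rnorm(n)
    zm <- params$lean_loading * g +
      sqrt(1 - params$lean_loading^2) * rnorm(n)
    lb <- params$bone_muscle_loading
    zb <- lb * zm + sqrt(1 - lb^2) * rnorm(n)
    list(z = cbind(fmi = zf, mmi = zm, bni = zb), labels = NULL)
  }
}

#' Generate a synthetic multi-wave cohort
#'
#' Draws one row per subject-wave observation.  Component masses are built
#' from the generating reference curves so that the bioimpedance identities
#' hold exactly: `fat_mass + lean_mass == weight`,
#' `muscle_mass + bone_mass == lean_mass`, `0 < water_mass < lean_mass`, and
#' `bfp == 100 * fat_mass / weight`.  Health indicators (abdominal
#' circumference, lipid panel, annual activity/sleep summaries) are tied to
#' the subject's fat z-score so that downstream group comparisons see the
#' reported direction of effects.  Missing values are *not* injected here;
#' see [inject_missing()].
#'
#' @param params A [cohort_params()] list.
#' @return A tibble of subject-wave records.  When planted centroids are
#'   present, a `cluster_true` column carries the per-subject latent label
#'   and the same map is attached as `attr(, "true_labels")`.
#' @export
generate_cohort <- function(params = cohort_params()) {
  stopifnot(inherits(params, "cohort_params"))
  n <- params$n_subjects
  if (n == 0L) {
    return(empty_cohort(has_labels = !is.null(params$cluster_centroids)))
  }
  withr::with_seed(derive_seed(params$seed, "cohort"), {
    subject_id <- sprintf("S%04d", seq_len(n))
    sex <- sample(c("male", "female"), n, replace = TRUE)
    base_age <- round(runif(n, params$age_range[1], params$age_range[2]), 1)
    zs <- draw_subject_z(params, n)
    present <- matrix(FALSE, n, params$waves)
    for (w in seq_len(params$waves)) {
      present[, w] <- runif(n) < params$participation[w]
    }
    rows <- vector("list", params$waves)
    for (w in seq_len(params$waves)) {
      idx <- which(present[, w])
      if (!length(idx)) next
      age <- round(base_age[idx] + (w - 1), 1)
      zw <- zs$z[idx, , drop = FALSE] +
        matrix(rnorm(3 * length(idx), sd = params$wave_jitter_sd), ncol = 3)
      rows[[w]] <- build_wave_records(params, subject_id[idx], sex[idx],
                                      w, age, zw,
                                      if (is.null(zs$labels)) NULL
                                      else zs$labels[idx])
    }
    cohort <- dplyr::bind_rows(rows)
    cohort <- dplyr::arrange(cohort, .data$subject_id, .data$wave)
  })
  if (!is.null(zs$labels)) {
    attr(cohort, "true_labels") <- tibble::tibble(
      subject_id = subject_id, cluster_true = zs$labels)
  }
  cohort
}

empty_cohort <- function(has_labels = FALSE) {
  out <- tibble::tibble(
    subject_id = character(), sex = character(), wave = integer(),
    age = double(), height = double(), weight = double(),
    fat_mass = double(), lean_mass = double(), muscle_mass = double(),
    bone_mass = double(), water_mass = double(), bfp = double(),
    ac = double(), tc = double(), tg = double(), hdlc = double(),
    steps_per_day = double(), activity_min = double(), sleep_min = double())
  if (has_labels) out$cluster_true <- integer()
  out
}

# one wave's records from z-vectors; relies on the generating curves
build_wave_records <- function(params, subject_id, sex, wave, age, zw,
                               labels) {
  m <- length(subject_id)
  cv <- function(s, idx, what) params$curves[[s]][[idx]][[what]]
  mu <- function(idx, what = "mean") {
    vapply(seq_len(m),
           function(i) poly_eval(cv(sex[i], idx, what), age[i]), 0)
  }
  fmi <- pmax(mu("fmi") + mu("fmi", "sd") * zw[, "fmi"], 0.3)
  mmi <- pmax(mu("mmi") + mu("mmi", "sd") * zw[, "mmi"], 4.0)
  bni <- pmax(mu("bni") + mu("bni", "sd") * zw[, "bni"], 0.2)
  height <- mu("height") +
    mu("height", "sd") * (0.4 * zw[, "mmi"] +
                            sqrt(1 - 0.16) * rnorm(m)) / 1  # cm
  height <- round(pmax(height, 95), 1)
  h2 <- (height / 100)^2
  fat <- fmi * h2
  muscle <- mmi * h2
  bone <- bni * h2
  lean <- muscle + bone
  weight <- fat + lean
  wfrac <- params$water_fraction + rnorm(m, sd = params$water_fraction_sd)
  wfrac <- pmin(pmax(wfrac, 0.55), 0.95)
  water <- wfrac * lean
  zf <- zw[, "fmi"]
  ac <- 50.5 + 1.6 * (age - 7) + 3.2 * zf + rnorm(m, sd = 1.8)
  tc <- 170 + 6 * zf + rnorm(m, sd = 22)
  hdlc <- pmax(62 - 4 * zf + rnorm(m, sd = 9), 25)
  tg <- pmax(75 + 18 * zf + rnorm(m, sd = 28), 20)
  # steps and activity carry no body-composition signal: subpopulation
  # differences are expressed through adiposity-linked indicators and sleep
  steps <- pmax(11500 + rnorm(m, sd = 2400), 2000)
  activity <- pmax(330 + rnorm(m, sd = 55), 60)
  sleep <- 540 - 12 * zf + rnorm(m, sd = 32)
  out <- tibble::tibble(
    subject_id = subject_id, sex = sex, wave = as.integer(wave), age = age,
    height = height, weight = weight, fat_mass = fat, lean_mass = lean,
    muscle_mass = muscle, bone_mass = bone, water_mass = water,
    bfp = 100 * fat / weight, ac = ac, tc = tc, tg = tg, hdlc = hdlc,
    steps_per_day = steps, activity_min = activity, sleep_min = sleep)
  if (!is.null(labels)) out$cluster_true <- as.integer(labels)
  out
}

#' The reference model implied by the generating curves
#'
#' Returns the generator's own true reference as a fitted-model object, so
#' that z-scores "under the generating reference" can be computed without
#' re-fitting.  Curves for the derived indices follow the generator's
#' conventions: LMI = MMI + BNI, TWI = `water_fraction` x LMI,
#' BMI = FMI + LMI for the means; the SD curves of the derived indices are
#' coefficient-level combinations (exact for perfectly correlated
#' components, a close approximation here).
#'
#' @param params A [cohort_params()] list.
#' @return A `bci_reference` object (see [fit_reference()]).
#' @export
generating_reference <- function(params = cohort_params()) {
  rows <- list()
  dom <- c(params$age_range[1], params$age_range[2] + params$waves - 1)
  for (sx in c("male", "female")) {
    crv <- params$curves[[sx]]
    lmi_mean <- crv$mmi$mean + crv$bni$mean
    lmi_sd <- crv$mmi$sd + params$bone_muscle_loading * crv$bni$sd
    twi_mean <- params$water_fraction * lmi_mean
    twi_sd <- params$water_fraction * lmi_sd
    bmi_mean <- crv$fmi$mean + lmi_mean
    bmi_sd <- crv$fmi$sd + 0.85 * lmi_sd
    curves <- list(
      fmi = list(mean = crv$fmi$mean, sd = crv$fmi$sd),
      mmi = list(mean = crv$mmi$mean, sd = crv$mmi$sd),
      bni = list(mean = crv$bni$mean, sd = crv$bni$sd),
      lmi = list(mean = lmi_mean, sd = lmi_sd),
      twi = list(mean = twi_mean, sd = twi_sd),
      bmi = list(mean = bmi_mean, sd = bmi_sd),
      height = list(mean = crv$height$mean, sd = crv$height$sd))
    for (idx in names(curves)) {
      cm <- curves[[idx]]$mean
      cs <- curves[[idx]]$sd
      rows[[length(rows) + 1L]] <- tibble::tibble(
        sex = sx, index = idx,
        curve = c("mean", "upper", "lower"),
        c0 = c(cm[1], cm[1] + cs[1], cm[1] - cs[1]),
        c1 = c(cm[2], cm[2] + cs[2], cm[2] - cs[2]),
        c2 = c(cm[3], cm[3] + cs[3], cm[3] - cs[3]),
        c3 = c(cm[4], cm[4] + cs[4], cm[4] - cs[4]),
        rss = 0)
    }
  }
  new_bci_reference(dplyr::bind_rows(rows), age_domain = dom)
}

#' Generate a wrist-worn device trace for one subject-wave
#'
#' Produces `n_days` consecutive daily records of category minutes
#' (sedentary/light/moderate/vigorous), monitored minutes, steps and sleep
#' minutes.  A configurable fraction of days are low-wear
#' (monitored/1440 <= 0.8) so that the wear-time screen has work to do.
#'
#' @param subject_id Subject identifier.
#' @param n_days Number of consecutive monitored days (>= 1).
#' @param seed Integer seed; the output is a deterministic function of the
#'   arguments.
#' @param wave Measurement-year index stored with each record.
#' @param start_date First monitored date.
#' @param low_wear_fraction Expected fraction of low-wear days.
#' @param mvpa_mean Subject's true mean daily moderate-to-vigorous minutes.
#' @param steps_mean,sleep_mean Subject's true mean daily steps / sleep
#'   minutes.
#' @return A tibble with one row per day.
#' @export
generate_device_days <- function(subject_id, n_days = 11, seed = 1L,
                                 wave = 1L,
                                 start_date = as.Date("2021-01-10"),
                                 low_wear_fraction = 0.12,
                                 mvpa_mean = 75, steps_mean = 11000,
                                 sleep_mean = 540) {
  stopifnot(n_days >= 1)
  assert_prob(low_wear_fraction, "low_wear_fraction")
  withr::with_seed(as.integer(seed), {
    low <- runif(n_days) < low_wear_fraction
    monitored <- ifelse(low, runif(n_days, 500, 1152),
                        pmin(round(rnorm(n_days, 1428, 10)), 1440))
    moderate <- pmax(round(0.72 * mvpa_mean + rnorm(n_days, sd = 9)), 0)
    vigorous <- pmax(round(0.28 * mvpa_mean + rnorm(n_days, sd = 5)), 0)
    light <- pmax(round(rnorm(n_days, 255, 35)), 0)
    # on low-wear days the device missed most of the day
    scale <- ifelse(low, monitored / 1440, 1)
    moderate <- round(moderate * scale)
    vigorous <- round(vigorous * scale)
    light <- round(light * scale)
    sedentary <- pmax(round(monitored) - light - moderate - vigorous, 0)
    steps <- pmax(round(rnorm(n_days, steps_mean, 2000) * scale), 0)
    sleep <- pmax(round(rnorm(n_days, sleep_mean, 25)), 0)
    tibble::tibble(
      subject_id = subject_id, wave = as.integer(wave),
      date = start_date + seq_len(n_days) - 1L,
      sedentary_min = as.numeric(sedentary), light_min = as.numeric(light),
      moderate_min = as.numeric(moderate),
      vigorous_min = as.numeric(vigorous),
      monitored_min = as.numeric(sedentary + light + moderate + vigorous),
      steps = as.numeric(steps), sleep_min = as.numeric(sleep))
  })
}

#' Generate device traces for every subject-wave of a cohort
#'
#' Each subject-wave gets an 11-day trace whose underlying daily means are
#' anchored to the cohort's annual summary columns (`steps_per_day`,
#' `sleep_min`) when present.  The subject's true mean MVPA is drawn once
#' per subject-wave from a distribution chosen so that roughly 81-85% of
#' subject-waves meet the 60 min/day guideline, rising slightly by wave.
#'
#' @param cohort A cohort tibble (one row per subject-wave).
#' @param n_days Days of wear per subject-wave.
#' @param seed Master seed.
#' @param low_wear_fraction Expected fraction of low-wear days.
#' @return A tibble of daily records for all subject-waves.
#' @export
generate_device_data <- function(cohort, n_days = 11, seed = 1L,
                                 low_wear_fraction = 0.12) {
  stopifnot(is.data.frame(cohort))
  if (!nrow(cohort)) {
    return(generate_device_days("x", 1, 1)[0, ])
  }
  traces <- vector("list", nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    sid <- cohort$subject_id[i]
    w <- cohort$wave[i]
    strm <- derive_seed(seed, paste0("device/", sid, "/", w))
    mvpa <- withr::with_seed(derive_seed(seed, paste0("mvpa/", sid, "/", w)),
                             72.5 + 1.5 * w + rnorm(1, sd = 16))
    traces[[i]] <- generate_device_days(
      sid, n_days = n_days, seed = strm, wave = w,
      start_date = as.Date("2021-01-10") + 365 * (w - 1),
      low_wear_fraction = low_wear_fraction,
      mvpa_mean = max(mvpa, 5),
      steps_mean = cohort$steps_per_day[i] %||% 11000,
      sleep_mean = cohort$sleep_min[i] %||% 540)
  }
  dplyr::bind_rows(traces)
}

#' Inject missing values into a cohort
#'
#' Each nullable field is independently set to `NA` with its stated rate
#' (missing completely at random).  The lipid panel (TC, TG, HDLC) is nulled
#' jointly under the `lipids` rate, mirroring a missed blood draw.
#' Non-nullable fields are never touched.
#'
#' @param records Cohort tibble.
#' @param missing_rates Named list/vector of rates; recognised names are
#'   `ac`, `lipids`, `steps`, `activity`, `sleep`, or any column name.
#' @param seed Integer seed.
#' @return The records with `NA`s injected.
#' @export
inject_missing <- function(records, missing_rates = default_missing_rates(),
                           seed = 1L) {
  stopifnot(is.data.frame(records))
  col_map <- list(ac = "ac", lipids = c("tc", "tg", "hdlc"),
                  steps = "steps_per_day", activity = "activity_min",
                  sleep = "sleep_min")
  out <- records
  withr::with_seed(derive_seed(seed, "missing"), {
    for (nm in names(missing_rates)) {
      rate <- missing_rates[[nm]]
      assert_prob(rate, nm)
      cols <- col_map[[nm]] %||% nm
      if (!all(cols %in% names(out))) {
        stop(sprintf("missing-rate name '%s' matches no cohort column", nm),
             call. = FALSE)
      }
      mask <- runif(nrow(out)) < rate
      for (cl in cols) out[[cl]][mask] <- NA_real_
    }
  })
  out
}

#' Read/write generator parameters as YAML
#'
#' Persists a [cohort_params()] list as YAML so simulation configurations
#' can live beside the data they produced.  The centroid matrix is stored
#' as rows plus a weights vector.
#'
#' @param params A [cohort_params()] list.
#' @param path File path (`.yaml`).
#' @return `read_cohort_params()` returns the restored `cohort_params`.
#' @export
write_cohort_params <- function(params, path) {
  stopifnot(inherits(params, "cohort_params"))
  payload <- unclass(params)
  if (!is.null(payload$cluster_centroids)) {
    m <- payload$cluster_centroids
    payload$cluster_centroids <- lapply(seq_len(nrow(m)),
                                        function(i) as.numeric(m[i, ]))
  }
  yaml::write_yaml(payload, path, precision = 15)
  invisible(path)
}

#' @rdname write_cohort_params
#' @export
read_cohort_params <- function(path) {
  p <- yaml::read_yaml(path)
  p$curves <- lapply(p$curves, function(sx) {
    lapply(sx, function(crv) lapply(crv, as.numeric))
  })
  cents <- NULL
  if (!is.null(p$cluster_centroids)) {
    cents <- do.call(rbind, lapply(p$cluster_centroids, as.numeric))
    colnames(cents) <- c("fmi", "mmi", "bni")
  }
  cohort_params(
    n_subjects = p$n_subjects, waves = p$waves,
    participation = as.numeric(p$participation),
    age_range = as.numeric(p$age_range), curves = p$curves,
    fat_loading = p$fat_loading, lean_loading = p$lean_loading,
    bone_muscle_loading = p$bone_muscle_loading,
    water_fraction = p$water_fraction,
    water_fraction_sd = p$water_fraction_sd, height_sd = p$height_sd,
    cluster_centroids = cents,
    cluster_weights = if (is.null(p$cluster_weights)) NULL
                      else as.numeric(p$cluster_weights),
    within_sd = p$within_sd, wave_jitter_sd = p$wave_jitter_sd,
    missing_rates = p$missing_rates, seed = p$seed)
}

#' Read/write cohort tables
#'
#' Plain-CSV persistence for cohort tables (one row per subject-wave) with
#' stable column types.
#'
#' @param cohort Cohort tibble.
#' @param path File path.
#' @return `read_cohort()` returns a tibble; `write_cohort()` its path,
#'   invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  tibble::as_tibble(df)
}
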