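#' Aggregate epoch-level device records to daily records
#'
#' Steps and activity minutes are credited to the calendar day containing
#' the epoch start (midnight delimiter).  A sleep episode is credited to the
#' day on which the wearer woke: episodes starting in `[18:00, 24:00)` of
#' day D count toward day D+1, episodes starting in `[00:00, 12:00]` of day
#' D count toward day D itself.  Episodes starting in `(12:00, 18:00)` fall
#' outside the device's sleep-recording window and are dropped with a
#' warning.  `monitored_min` is the sum of the four activity-category
#' minutes.
#'
#' @param epochs Tibble with columns `subject_id`, `timestamp`
#'   (`POSIXct` or `"YYYY-MM-DD HH:MM[:SS]"` strings, treated as local clock
#'   time), `kind` (`"activity"`, `"steps"`, `"sleep"`), `category`
#'   (activity only: sedentary/light/moderate/vigorous), `duration` (min,
#'   activity and sleep) and `steps` (steps rows only).
#' @return A tibble of daily records (one row per subject-day).
#' @export
aggregate_daily <- function(epochs) {
  stopifnot(is.data.frame(epochs))
  ts <- epochs$timestamp
  if (!inherits(ts, "POSIXct")) {
    ts <- as.POSIXct(ts, tz = "UTC")
    if (any(is.na(ts))) stop("malformed timestamps", call. = FALSE)
  }
  epochs$..ts <- ts
  epochs$..date <- as.Date(ts, tz = "UTC")

  act <- epochs[epochs$kind == "activity", , drop = FALSE]
  if (nrow(act)) {
    act <- act[order(act$subject_id, act$..ts), , drop = FALSE]
    for (sid in unique(act$subject_id)) {
      a <- act[act$subject_id == sid, , drop = FALSE]
      if (nrow(a) > 1) {
        ends <- a$..ts + a$duration * 60
        clash <- which(a$..ts[-1] < ends[-nrow(a)])
        if (length(clash)) {
          stop(sprintf(
            "overlapping activity epochs for %s at %s",
            sid, paste(format(a$..ts[clash + 1]), collapse = ", ")),
            call. = FALSE)
        }
      }
    }
  }

  slp <- epochs[epochs$kind == "sleep", , drop = FALSE]
  if (nrow(slp)) {
    hrs <- as.numeric(format(slp$..ts, "%H")) +
      as.numeric(format(slp$..ts, "%M")) / 60
    outside <- hrs > 12 & hrs < 18
    if (any(outside)) {
      warning(sum(outside),
              " sleep episode(s) outside the 18:00-12:00 window dropped",
              call. = FALSE)
      slp <- slp[!outside, , drop = FALSE]
      hrs <- hrs[!outside]
    }
    slp$..date <- slp$..date + ifelse(hrs >= 18, 1L, 0L)
  }

  stp <- epochs[epochs$kind == "steps", , drop = FALSE]

  keys <- unique(rbind(act[, c("subject_id", "..date")],
                       slp[, c("subject_id", "..date")],
                       stp[, c("subject_id", "..date")]))
  keys <- keys[order(keys$subject_id, keys$..date), , drop = FALSE]

  cat_min <- function(day_rows, cat) {
    sum(day_rows$duration[day_rows$category == cat], na.rm = TRUE)
  }
  out <- lapply(seq_len(nrow(keys)), function(i) {
    sid <- keys$subject_id[i]
    d <- keys$..date[i]
    a <- act[act$subject_id == sid & act$..date == d, , drop = FALSE]
    s <- slp[slp$subject_id == sid & slp$..date == d, , drop = FALSE]
    p <- stp[stp$subject_id == sid & stp$..date == d, , drop = FALSE]
    mins <- vapply(c("sedentary", "light", "moderate", "vigorous"),
                   function(cc) cat_min(a, cc), 0)
    tibble::tibble(
      subject_id = sid, date = d,
      sedentary_min = mins[["sedentary"]], light_min = mins[["light"]],
      moderate_min = mins[["moderate"]], vigorous_min = mins[["vigorous"]],
      monitored_min = sum(mins),
      steps = sum(p$steps, na.rm = TRUE),
      sleep_min = sum(s$duration, na.rm = TRUE))
  })
  dplyr::bind_rows(out)
}

split_kept <- function(days, keep, reason) {
  excluded <- days[!keep, , drop = FALSE]
  if (nrow(excluded)) excluded$reason <- reason[!keep]
  else excluded$reason <- character()
  list(kept = days[keep, , drop = FALSE], excluded = excluded)
}

subject_key <- function(days) {
  if ("wave" %in% names(days)) {
    paste(days$subject_id, days$wave, sep = "\r")
  } else {
    days$subject_id
  }
}

#' Trim the first and last days of each wear period
#'
#' Device behaviour on the days immediately after hand-out and before
#' collection is unreliable, so the first `n_edge` and last `n_edge`
#' calendar days of each subject-wave's wear period are excluded.  Weekdays
#' and holidays are treated alike.  A subject-wave with `<= 2 * n_edge` days
#' loses all its days, with a warning.
#'
#' @param days Daily records ([aggregate_daily()] output or generated).
#' @param n_edge Days trimmed from each end.
#' @return `list(kept, excluded)`; excluded rows carry reason `"edge_day"`.
#' @export
trim_edge_days <- function(days, n_edge = 3) {
  stopifnot(is.data.frame(days), n_edge >= 0)
  if (n_edge == 0 || !nrow(days)) {
    return(split_kept(days, rep(TRUE, nrow(days)), character(nrow(days))))
  }
  key <- subject_key(days)
  keep <- rep(TRUE, nrow(days))
  emptied <- character()
  for (k in unique(key)) {
    rows <- which(key == k)
    dts <- sort(unique(days$date[rows]))
    if (length(dts) <= 2 * n_edge) {
      keep[rows] <- FALSE
      emptied <- c(emptied, days$subject_id[rows[1]])
      next
    }
    edge <- c(head(dts, n_edge), tail(dts, n_edge))
    keep[rows][days$date[rows] %in% edge] <- FALSE
  }
  if (length(emptied)) {
    warning("all days edge-trimmed for subject(s): ",
            paste(unique(emptied), collapse = ", "), call. = FALSE)
  }
  split_kept(days, keep, rep("edge_day", nrow(days)))
}

#' Relative daily durations
#'
#' Each minute field divided by 1440 min; `p_total_activity` is the
#' light + moderate + vigorous share of the day.
#'
#' @param days Daily records.
#' @return The input with proportion columns appended.
#' @export
relative_durations <- function(days) {
  dplyr::mutate(
    days,
    p_sedentary = .data$sedentary_min / 1440,
    p_light = .data$light_min / 1440,
    p_moderate = .data$moderate_min / 1440,
    p_vigorous = .data$vigorous_min / 1440,
    p_monitored = .data$monitored_min / 1440,
    p_total_activity = (.data$light_min + .data$moderate_min +
                          .data$vigorous_min) / 1440)
}

#' Wear-time filters
#'
#' A day is kept iff the monitored share of the day is strictly greater
#' than `monitored_threshold` (default 0.8) *and* the total-activity share
#' is strictly greater than `activity_threshold` (default 0.1).  The
#' exclusion reason records the first failed criterion, in that order.
#'
#' @param days Daily records (after edge trimming).
#' @param monitored_threshold Minimum monitored proportion (exclusive).
#' @param activity_threshold Minimum total-activity proportion (exclusive).
#' @return `list(kept, excluded)` with reasons `"low_monitor"` /
#'   `"low_activity"`.
#' @export
apply_wear_filters <- function(days, monitored_threshold = 0.8,
                               activity_threshold = 0.1) {
  rd <- relative_durations(days)
  low_mon <- !(rd$p_monitored > monitored_threshold)
  low_act <- !(rd$p_total_activity > activity_threshold)
  reason <- ifelse(low_mon, "low_monitor",
                   ifelse(low_act, "low_activity", ""))
  split_kept(days, !(low_mon | low_act), reason)
}

#' Mean +/- 2 SD acceptance filter
#'
#' Values within two sample SDs of the mean of the supplied values are
#' acceptable (inclusive bounds).  The mean and SD are computed once over
#' all supplied values (single pass, no re-computation after removal).
#'
#' @param values Numeric vector (>= 2 values).
#' @param n_sd Number of SDs defining the acceptance band.
#' @return `list(keep, bounds, mean, sd)` where `keep` is a logical mask.
#' @export
apply_sd_filter <- function(values, n_sd = 2) {
  if (length(values) < 2) stop("need at least 2 values", call. = FALSE)
  mu <- mean(values)
  s <- sd(values)
  if (!is.finite(s) || s == 0) {
    warning("zero SD; all values kept", call. = FALSE)
    return(list(keep = rep(TRUE, length(values)),
                bounds = c(mu, mu), mean = mu, sd = 0))
  }
  bounds <- c(mu - n_sd * s, mu + n_sd * s)
  list(keep = values >= bounds[1] & values <= bounds[2],
       bounds = bounds, mean = mu, sd = s)
}

#' Per-participant-year summaries over retained days
#'
#' Arithmetic means of steps, total activity minutes, MVPA minutes and
#' sleep minutes over each subject-wave's retained days.  Subject-waves
#' named in `roster` with no retained days get an all-`NA` summary row (the
#' missingness then flows to the imputation stage).
#'
#' @param retained Retained daily records.
#' @param roster Optional tibble of `subject_id` (+ `wave`) defining the
#'   full set of subject-waves to summarise.
#' @return Tibble with one row per subject-wave.
#' @export
participant_year_means <- function(retained, roster = NULL) {
  wave_col <- "wave" %in% names(retained)
  grp <- if (wave_col) c("subject_id", "wave") else "subject_id"
  summ <- dplyr::summarise(
    dplyr::group_by(retained, dplyr::across(dplyr::all_of(grp))),
    n_days = dplyr::n(),
    steps = mean(.data$steps),
    activity_min = mean(.data$light_min + .data$moderate_min +
                          .data$vigorous_min),
    mvpa_min = mean(.data$moderate_min + .data$vigorous_min),
    sleep_min = mean(.data$sleep_min),
    .groups = "drop")
  if (!is.null(roster)) {
    roster <- unique(roster[, intersect(grp, names(roster)), drop = FALSE])
    summ <- dplyr::left_join(roster, summ, by = intersect(grp, names(roster)))
    summ$n_days[is.na(summ$n_days)] <- 0L
  }
  summ
}

#' Screen a table of daily device records
#'
#' Sequential screening: (1) edge-day trimming; (2) wear-time filters
#' (monitored share > 0.8, total-activity share > 0.1); (3) mean +/- 2 SD
#' acceptance bands for daily steps and sleep minutes, computed over the
#' days that survived the wear filters — cohort-wide within each
#' measurement year by default, or per participant with
#' `sd_scope = "subject"`.  Every input day lands in exactly one of
#' `retained` or `excluded` (with the first failed criterion as its
#' reason).
#'
#' @param days Daily records for the whole screening population.
#' @param n_edge Edge days trimmed per wear period.
#' @param monitored_threshold,activity_threshold Wear-filter thresholds.
#' @param n_sd SD multiple for the outlier bands.
#' @param sd_scope `"cohort"` (per measurement year) or `"subject"`.
#' @return A `screening_result` list: `retained`, `excluded` (with
#'   `reason`), `summaries` (per subject-wave means over retained days,
#'   `NA` where none remain) and `sd_bounds`.
#' @export
screen_device_days <- function(days, n_edge = 3, monitored_threshold = 0.8,
                               activity_threshold = 0.1, n_sd = 2,
                               sd_scope = c("cohort", "subject")) {
  sd_scope <- match.arg(sd_scope)
  stopifnot(is.data.frame(days))
  st1 <- trim_edge_days(days, n_edge = n_edge)
  st2 <- apply_wear_filters(st1$kept, monitored_threshold,
                            activity_threshold)
  surv <- st2$kept
  bounds <- list()
  if (nrow(surv) >= 2) {
    grp <- if (sd_scope == "subject") subject_key(surv)
           else if ("wave" %in% names(surv)) as.character(surv$wave)
           else rep("all", nrow(surv))
    keep_steps <- rep(TRUE, nrow(surv))
    keep_sleep <- rep(TRUE, nrow(surv))
    for (g in unique(grp)) {
      rows <- which(grp == g)
      if (length(rows) < 2) next
      fs <- apply_sd_filter(surv$steps[rows], n_sd)
      fl <- apply_sd_filter(surv$sleep_min[rows], n_sd)
      keep_steps[rows] <- fs$keep
      keep_sleep[rows] <- fl$keep
      bounds[[g]] <- tibble::tibble(
        group = g, measure = c("steps", "sleep_min"),
        lower = c(fs$bounds[1], fl$bounds[1]),
        upper = c(fs$bounds[2], fl$bounds[2]))
    }
    reason <- ifelse(!keep_steps, "steps_outlier",
                     ifelse(!keep_sleep, "sleep_outlier", ""))
    st3 <- split_kept(surv, keep_steps & keep_sleep, reason)
  } else {
    st3 <- split_kept(surv, rep(TRUE, nrow(surv)), character(nrow(surv)))
  }
  excluded <- dplyr::bind_rows(st1$excluded, st2$excluded, st3$excluded)
  roster <- unique(days[, intersect(c("subject_id", "wave"), names(days)),
                        drop = FALSE])
  structure(
    list(retained = st3$kept, excluded = excluded,
         summaries = participant_year_means(st3$kept, roster = roster),
         sd_bounds = dplyr::bind_rows(bounds)),
    class = "screening_result")
}

#' @export
print.screening_result <- function(x, ...) {
  cat(sprintf("<screening_result> %d retained / %d excluded days\n",
              nrow(x$retained), nrow(x$excluded)))
  if (nrow(x$excluded)) print(table(x$excluded$reason))
  invisible(x)
}

#' Read/write daily device records
#'
#' Plain-CSV persistence for daily device records; `read_device_days()`
#' restores the `date` column to `Date`.
#'
#' @param days Daily-record tibble.
#' @param path File path.
#' @return `read_device_days()` returns a tibble.
#' @export
write_device_days <- function(days, path) {
  utils::write.csv(days, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_device_days
#' @export
read_device_days <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$date <- as.Date(df$date)
  tibble::as_tibble(df)
}

#' Share of subject-waves meeting the MVPA guideline
#'
#' Fraction of subject-wave summaries whose mean daily
#' moderate-to-vigorous activity is at or above `threshold` minutes
#' (the WHO guideline for children is 60 min/day).  Summaries with no
#' retained days (`NA` MVPA) are excluded from the denominator.
#'
#' @param summaries Output of [participant_year_means()] (needs
#'   `mvpa_min`).
#' @param threshold Guideline threshold in minutes.
#' @return Proportion in `[0, 1]`.
#' @export
mvpa_compliance <- function(summaries, threshold = 60) {
  if (!nrow(summaries)) stop("no summaries supplied", call. = FALSE)
  v <- summaries$mvpa_min
  v <- v[!is.na(v)]
  if (!length(v)) stop("no non-missing MVPA summaries", call. = FALSE)
  mean(v >= threshold)
}
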