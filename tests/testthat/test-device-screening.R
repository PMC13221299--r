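epoch <- function(sid, ts, kind, category = NA, duration = NA, steps = NA) {
  tibble::tibble(subject_id = sid, timestamp = ts, kind = kind,
                 category = category, duration = duration, steps = steps)
}

test_that("daily aggregation credits epochs to the right calendar day", {
  e <- epoch("A", "2021-01-05 10:00", "activity", "light", 30)
  d <- aggregate_daily(e)
  expect_equal(d$light_min, 30)
  expect_equal(d$monitored_min, 30)
  expect_identical(d$date, as.Date("2021-01-05"))
  # a full day of the four categories sums to 1440 monitored minutes
  full <- dplyr::bind_rows(
    epoch("A", "2021-01-05 00:00", "activity", "sedentary", 900),
    epoch("A", "2021-01-05 15:00", "activity", "light", 400),
    epoch("A", "2021-01-05 21:40", "activity", "moderate", 100),
    epoch("A", "2021-01-05 23:20", "activity", "vigorous", 40))
  expect_equal(aggregate_daily(full)$monitored_min, 1440)
  # overlapping activity epochs are an error
  clash <- dplyr::bind_rows(
    epoch("A", "2021-01-05 10:00", "activity", "light", 60),
    epoch("A", "2021-01-05 10:30", "activity", "moderate", 30))
  expect_error(aggregate_daily(clash), "overlapping")
})

test_that("sleep episodes are credited to the wake day", {
  # 21:00 day D -> 06:30 day D+1, 570 min, credited to D+1
  e <- epoch("A", "2021-01-05 21:00", "sleep", duration = 570)
  d <- aggregate_daily(e)
  expect_identical(d$date, as.Date("2021-01-06"))
  expect_equal(d$sleep_min, 570)
  # an early-morning episode stays on its own day
  e2 <- epoch("A", "2021-01-06 01:30", "sleep", duration = 300)
  expect_identical(aggregate_daily(e2)$date, as.Date("2021-01-06"))
  # afternoon starts are outside the recording window
  e3 <- epoch("A", "2021-01-06 14:00", "sleep", duration = 60)
  expect_warning(d3 <- aggregate_daily(e3), "window")
  expect_identical(nrow(d3), 0L)
})

test_that("edge-day trimming drops the first and last three days", {
  d <- generate_device_days("A", n_days = 11, seed = 1)
  tr <- trim_edge_days(d)
  expect_identical(nrow(tr$kept), 5L)
  expect_identical(sort(tr$kept$date), sort(d$date[4:8]))
  expect_true(all(tr$excluded$reason == "edge_day"))
  # <= 2 * n_edge days: everything goes, with a warning
  expect_warning(tr6 <- trim_edge_days(d[1:6, ]), "edge-trimmed")
  expect_identical(nrow(tr6$kept), 0L)
  # n_edge = 0 is the identity
  expect_identical(trim_edge_days(d, n_edge = 0)$kept, d)
})

test_that("relative durations divide by 1440", {
  d <- generate_device_days("A", n_days = 1, seed = 2)
  d$monitored_min <- 1296
  d$light_min <- 100
  d$moderate_min <- 30
  d$vigorous_min <- 14
  rd <- relative_durations(d)
  expect_equal(rd$p_monitored, 0.9)
  expect_equal(rd$p_total_activity, 0.1)
  d0 <- d
  d0[, c("sedentary_min", "light_min", "moderate_min", "vigorous_min",
         "monitored_min")] <- 0
  rd0 <- relative_durations(d0)
  expect_true(all(rd0[, c("p_monitored", "p_total_activity")] == 0))
})

test_that("wear filters are strict and report the first failed criterion", {
  d <- generate_device_days("A", n_days = 3, seed = 3)
  d$sedentary_min <- c(900, 1156, 1000)
  d$light_min <- c(200, 100, 150)
  d$moderate_min <- c(40, 30, 100)
  d$vigorous_min <- c(12, 14, 50)
  d$monitored_min <- c(1152, 1300, 1300)  # 0.8 exactly; 0.90 with 0.1 activity; good
  f <- apply_wear_filters(d)
  expect_identical(nrow(f$kept), 1L)
  expect_identical(f$excluded$reason, c("low_monitor", "low_activity"))
})

test_that("the +/-2 SD filter is single-pass, inclusive and audited", {
  v <- c(rep(10, 9), 100)
  f <- apply_sd_filter(v)
  expect_equal(f$mean, 19)
  expect_equal(f$sd, sqrt(810), tolerance = 1e-12)  # 28.46
  expect_equal(f$bounds, 19 + c(-2, 2) * sqrt(810))
  expect_identical(sum(f$keep), 9L)
  expect_false(f$keep[10])
  expect_warning(fz <- apply_sd_filter(rep(5, 4)), "zero SD")
  expect_true(all(fz$keep))
  # a value exactly on the boundary is kept
  vb <- c(-1, 1)  # mean 0, sd sqrt(2), bounds +/- 2 sqrt 2
  vb2 <- c(vb, 0)
  f2 <- apply_sd_filter(c(0, 1, -1))
  expect_true(all(f2$keep))
  expect_true(apply_sd_filter(c(0, 2, -2, 0))$keep[2])
})

test_that("participant-year means average retained days, NA when empty", {
  d <- generate_device_days("A", n_days = 2, seed = 4)
  d$steps <- c(6000, 8000)
  s <- participant_year_means(d)
  expect_equal(s$steps, 7000)
  expect_equal(s$sleep_min, mean(d$sleep_min), tolerance = 1e-12)
  roster <- tibble::tibble(subject_id = c("A", "B"), wave = 1L)
  s2 <- participant_year_means(d, roster = roster)
  expect_identical(s2$n_days, c(2L, 0L))
  expect_true(is.na(s2$steps[2]))
})

test_that("MVPA compliance is the fraction of summaries at the guideline", {
  s <- tibble::tibble(mvpa_min = c(70, 80, 90, 100, 61, 20))
  expect_equal(mvpa_compliance(s), 5 / 6)
  expect_equal(mvpa_compliance(tibble::tibble(mvpa_min = c(61, 70))), 1)
  expect_equal(mvpa_compliance(tibble::tibble(mvpa_min = c(10, 20))), 0)
  expect_error(mvpa_compliance(tibble::tibble(mvpa_min = numeric())), "no summaries")
})

test_that("screening partitions the input and ignores row order", {
  d <- generate_device_data(
    generate_cohort(cohort_params(n_subjects = 15, seed = 2)),
    seed = 5, low_wear_fraction = 0.3)
  scr <- screen_device_days(d)
  expect_identical(nrow(scr$retained) + nrow(scr$excluded), nrow(d))
  key <- function(x) sort(paste(x$subject_id, x$wave, x$date))
  expect_identical(sort(c(key(scr$retained), key(scr$excluded))), key(d))
  shuffled <- d[sample(nrow(d)), ]
  scr2 <- screen_device_days(shuffled)
  expect_identical(key(scr2$retained), key(scr$retained))
  expect_identical(sort(table(scr2$excluded$reason)),
                   sort(table(scr$excluded$reason)))
  # loosening the monitored threshold never shrinks the wear-filtered set
  strict <- apply_wear_filters(d, monitored_threshold = 0.8)
  loose <- apply_wear_filters(d, monitored_threshold = 0.5)
  expect_true(all(key(strict$kept) %in% key(loose$kept)))
})

test_that("the shipped 3-subject fixture yields its designed exclusions", {
  path <- system.file("extdata", "device_screening_fixture.csv",
                      package = "pedbc")
  days <- read_device_days(path)
  scr <- screen_device_days(days)
  counts <- table(scr$excluded$reason)
  expect_identical(counts[["edge_day"]], 18L)
  expect_identical(counts[["low_monitor"]], 1L)
  expect_identical(counts[["low_activity"]], 1L)
  expect_identical(counts[["steps_outlier"]], 1L)
  expect_identical(counts[["sleep_outlier"]], 1L)
  expect_identical(nrow(scr$retained), 11L)
})
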