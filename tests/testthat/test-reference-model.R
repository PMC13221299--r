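test_that("compute_bci is mass over squared height in metres", {
  expect_identical(compute_bci(0, 150), 0)
  expect_equal(compute_bci(20, 125), 12.8)
  expect_equal(compute_bci(20, 160), 7.8125)
  expect_error(compute_bci(20, 0), "positive")
  expect_error(compute_bci(-1, 150), "non-negative")
})

test_that("bin statistics use floored age and the sample SD", {
  d <- tibble::tibble(sex = "male", age = c(8.2, 8.9), fmi = c(4, 6))
  b <- bin_stats(d, indices = "fmi")
  expect_identical(b$age_int, 8L)
  expect_equal(b$mean, 5)
  expect_equal(b$sd, sqrt(2))
  # single-record bins are dropped with a warning
  d2 <- tibble::tibble(sex = "male", age = c(8.2, 8.9, 9.4),
                       fmi = c(4, 6, 5))
  expect_warning(b2 <- bin_stats(d2, "fmi"), "n < 2")
  expect_identical(b2$age_int, 8L)
  # degenerate equal values give sd 0
  d3 <- tibble::tibble(sex = "male", age = c(10.1, 10.7), fmi = c(5, 5))
  expect_equal(bin_stats(d3, "fmi")$sd, 0)
})

test_that("the cubic fit interpolates exact polynomial bin data", {
  ages <- 7:14
  f <- function(a) 0.01 * a^3 - 0.2 * a^2 + a + 3
  bins <- tibble::tibble(sex = "male", age_int = ages, index = "fmi",
                         n = 50, mean = f(ages), sd = 1)
  m <- fit_reference(bins)
  cf <- m$coefficients
  expect_equal(unlist(cf[cf$curve == "mean", c("c0", "c1", "c2", "c3")]),
               c(c0 = 3, c1 = 1, c2 = -0.2, c3 = 0.01), tolerance = 1e-8)
  expect_equal(cf$c0[cf$curve == "upper"] - cf$c0[cf$curve == "lower"], 2,
               tolerance = 1e-7)
  # constant series: non-constant coefficients vanish
  bins2 <- tibble::tibble(sex = "f", age_int = ages, index = "fmi",
                          n = 50, mean = 5, sd = 0.5)
  m2 <- fit_reference(bins2)
  ref <- evaluate_reference(m2, "f", "fmi", 10)
  expect_equal(ref$mean, 5, tolerance = 1e-8)
  expect_equal(ref$sd, 0.5, tolerance = 1e-8)
  expect_error(fit_reference(bins[1:3, ]), "distinct integer ages")
})

test_that("fitted coefficients solve the least-squares normal equations", {
  withr::with_seed(5, {
    ages <- 7:14
    y <- 0.3 * ages + rnorm(8)
    bins <- tibble::tibble(sex = "male", age_int = ages, index = "bmi",
                           n = 30, mean = y, sd = 1)
    m <- fit_reference(bins)
    X <- cbind(1, ages, ages^2, ages^3)
    beta <- solve(t(X) %*% X, t(X) %*% y)  # explicit normal equations
    cf <- m$coefficients
    got <- unlist(cf[cf$curve == "mean", c("c0", "c1", "c2", "c3")])
    expect_equal(unname(got), as.numeric(beta), tolerance = 1e-8)
  })
})

test_that("evaluation rounds age to 0.1 and matches a Horner oracle", {
  ages <- 7:14
  bins <- tibble::tibble(sex = "male", age_int = ages, index = "fmi",
                         n = 30, mean = 0.02 * ages^3 - 0.1 * ages^2 + 4,
                         sd = 0.3 + 0.02 * ages)
  m <- fit_reference(bins)
  expect_equal(evaluate_reference(m, "male", "fmi", 9.94)$mean,
               evaluate_reference(m, "male", "fmi", 9.9)$mean)
  cf <- m$coefficients
  cm <- as.numeric(cf[cf$curve == "mean", c("c0", "c1", "c2", "c3")])
  horner <- ((cm[4] * 8.3 + cm[3]) * 8.3 + cm[2]) * 8.3 + cm[1]
  expect_equal(evaluate_reference(m, "male", "fmi", 8.3)$mean, horner,
               tolerance = 1e-12)
  expect_error(evaluate_reference(m, "male", "fmi", 20), "domain")
  expect_equal(evaluate_reference(m, "male", "fmi", 20, clamp = TRUE)$mean,
               evaluate_reference(m, "male", "fmi", 14.9)$mean)
})

test_that("z-scores centre and scale against the reference", {
  bins <- tibble::tibble(sex = "male", age_int = 7:14, index = "fmi",
                         n = 30, mean = 5, sd = 0.5)
  m <- fit_reference(bins)
  expect_equal(zscore(m, 5, "male", "fmi", 10), 0, tolerance = 1e-8)
  expect_equal(zscore(m, 5.5, "male", "fmi", 10), 1, tolerance = 1e-7)
  expect_equal(zscore(m, 6.2, "male", "fmi", 10), 2.4, tolerance = 1e-7)
})

test_that("the exported grid matches evaluation and the model round-trips", {
  bins <- tidyr::expand_grid(sex = c("male", "female"), age_int = 7:13,
                             index = c("fmi", "mmi"))
  bins$n <- 40
  bins$mean <- 4 + 0.2 * bins$age_int + (bins$index == "mmi") * 6
  bins$sd <- 0.5 + 0.02 * bins$age_int
  m <- fit_reference(bins)
  tab <- export_reference_table(m)
  expect_identical(nrow(tab), 4L * length(seq(7, 13.9, by = 0.1)))
  # table means at integer ages equal direct evaluation
  at9 <- tab[tab$sex == "male" & tab$index == "fmi" & tab$age == 9, ]
  ref <- evaluate_reference(m, "male", "fmi", 9)
  expect_equal(at9$mean, ref$mean)
  expect_equal(at9$sd, ref$sd)
  # a domain spanning exactly [7, 14] yields 71 ages per sex x index
  m14 <- m
  m14$age_domain <- c(7, 14)
  expect_identical(nrow(export_reference_table(m14)), 4L * 71L)
  # JSON round-trip reproduces identical z-scores
  path <- withr::local_tempfile(fileext = ".json")
  write_reference(m, path)
  m2 <- read_reference(path)
  ages <- seq(7, 13.9, by = 0.37)
  expect_identical(zscore(m2, 6, "female", "mmi", ages),
                   zscore(m, 6, "female", "mmi", ages))
})

test_that("adding a constant to an index shifts the mean curve only", {
  withr::with_seed(8, {
    d <- tibble::tibble(sex = "male", age = runif(400, 7, 13.9),
                        fmi = 4 + rnorm(400, sd = 0.8))
    m1 <- fit_reference(bin_stats(d, "fmi"))
    d$fmi <- d$fmi + 2.5
    m2 <- fit_reference(bin_stats(d, "fmi"))
    r1 <- evaluate_reference(m1, "male", "fmi", c(8, 10.5, 12))
    r2 <- evaluate_reference(m2, "male", "fmi", c(8, 10.5, 12))
    expect_equal(r2$mean, r1$mean + 2.5, tolerance = 1e-8)
    expect_equal(r2$sd, r1$sd, tolerance = 1e-8)
  })
})

test_that("self-standardized z-scores are centred near 0 with near-unit SD", {
  co <- add_bci(generate_cohort(cohort_params(n_subjects = 2100, waves = 1,
                                              participation = 1, seed = 4)))
  z <- cohort_zscores(build_reference(co), co)
  z$age_int <- floor(z$age)
  for (idx in zcols()) {
    per_bin <- dplyr::summarise(
      dplyr::group_by(z, .data$sex, .data$age_int),
      m = mean(.data[[idx]]), s = sd(.data[[idx]]), n = dplyr::n(),
      .groups = "drop")
    per_bin <- per_bin[per_bin$n >= 50, ]
    expect_true(all(per_bin$m > -0.3 & per_bin$m < 0.3))
    expect_true(all(per_bin$s > 0.7 & per_bin$s < 1.3))
  }
})
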