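make_cohort <- function(psi, time = NULL, event = NULL) {
  n <- length(psi)
  tibble::tibble(
    patient_id = sprintf("p%02d", seq_len(n)),
    time_days = time %||% rep(100, n),
    event = event %||% rep(1L, n),
    psi = psi)
}

test_that("PSI stratification puts the boundary in the high stratum", {
  strat <- stratify_by_psi(make_cohort(c(2, 5)), threshold = 4.07)
  expect_equal(strat$stratum, c("low", "high"))
  strat2 <- stratify_by_psi(make_cohort(c(4.07, 4.0699)), threshold = 4.07)
  expect_equal(strat2$stratum, c("high", "low"))
})

test_that("empty strata and missing PSI are handled explicitly", {
  expect_error(stratify_by_psi(make_cohort(c(1, 2, 3)), 4.07),
    "empty stratum: high")
  expect_error(stratify_by_psi(make_cohort(c(5, 6)), 4.07),
    "empty stratum: low")
  expect_message(
    strat <- stratify_by_psi(make_cohort(c(2, 5, NA)), 4.07),
    "Excluded 1")
  expect_equal(nrow(strat), 2L)
})

test_that("product-limit estimate matches the hand calculation", {
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))
  expect_equal(km_median(km), 2)
  expect_true(all(diff(km$surv) <= 0))

  # censored-only data: flat curve, undefined median
  km2 <- km_estimate(c(5, 10, 20), c(0, 0, 0))
  expect_true(all(km2$surv == 1))
  expect_true(is.na(km_median(km2)))

  expect_error(km_estimate(numeric(0), numeric(0)),
    class = "splicescreen_validation_error")
  expect_error(km_estimate(c(0, 1), c(1, 1)),
    class = "splicescreen_validation_error")
})

test_that("KM agrees with the survival package at all event times", {
  withr::local_seed(51)
  for (rep in 1:5) {
    n <- 50
    time <- round(rexp(n, 1 / 500)) + 1
    event <- rbinom(n, 1, 0.7)
    km <- km_estimate(time, event)
    sf <- survival::survfit(survival::Surv(time, event) ~ 1)
    ours <- km$surv[km$n_event > 0]
    theirs <- sf$surv[sf$n.event > 0]
    expect_equal(ours, theirs, tolerance = 1e-12)
  }
})

test_that("KM accumulates exactly the observed number of deaths", {
  withr::local_seed(52)
  time <- round(rexp(40, 1 / 300)) + 1
  event <- rbinom(40, 1, 0.6)
  km <- km_estimate(time, event)
  expect_equal(sum(km$n_event), sum(event))
  expect_equal(attr(km, "n_events"), sum(event))
})

test_that("log-rank is zero under identical strata and symmetric in labels", {
  time <- c(10, 20, 30, 40)
  df <- tibble::tibble(
    time_days = c(time, time),
    event = rep(1L, 8),
    stratum = rep(c("high", "low"), each = 4))
  lr <- logrank_test(df)
  expect_equal(lr$chi_square, 0)
  expect_equal(lr$p, 1)
  expect_equal(sum(lr$table$observed), sum(lr$table$expected))

  withr::local_seed(53)
  df2 <- tibble::tibble(
    time_days = round(rexp(40, 1 / 200)) + 1,
    event = rbinom(40, 1, 0.8),
    stratum = rep(c("high", "low"), 20))
  df2_swap <- dplyr::mutate(df2,
    stratum = ifelse(.data$stratum == "high", "low", "high"))
  expect_equal(logrank_test(df2)$chi_square, logrank_test(df2_swap)$chi_square,
    tolerance = 1e-12)
  expect_equal(logrank_test(df2)$p, logrank_test(df2_swap)$p, tolerance = 1e-12)
})

test_that("log-rank agrees with the survival package and is rank-invariant", {
  withr::local_seed(54)
  for (rep in 1:5) {
    n <- 60
    df <- tibble::tibble(
      time_days = round(rexp(n, 1 / 300)) + 1,
      event = rbinom(n, 1, 0.7),
      stratum = sample(rep(c("high", "low"), n / 2)))
    lr <- logrank_test(df)
    sv <- survival::survdiff(
      survival::Surv(time_days, event) ~ stratum, data = df)
    expect_equal(lr$chi_square, sv$chisq, tolerance = 1e-9)

    # monotone time transformation leaves the rank-based statistic unchanged
    df_t <- dplyr::mutate(df, time_days = .data$time_days^2 / 100 + 1)
    expect_equal(logrank_test(df_t)$chi_square, lr$chi_square, tolerance = 1e-9)
  }
})

test_that("no events gives statistic 0, p 1, with a warning", {
  df <- tibble::tibble(time_days = c(5, 6, 7, 8), event = 0L,
    stratum = c("high", "high", "low", "low"))
  expect_warning(lr <- logrank_test(df), "No events")
  expect_equal(lr$chi_square, 0)
  expect_equal(lr$p, 1)
})

test_that("cutpoint scan handles degenerate inputs and a single threshold", {
  withr::local_seed(55)
  expect_error(scan_cutpoints(make_cohort(rep(3, 30),
    time = round(rexp(30, 1 / 200)) + 1, event = rbinom(30, 1, 0.8))),
    class = "splicescreen_validation_error")

  coh <- make_cohort(runif(60, 0, 20),
    time = round(rexp(60, 1 / 300)) + 1, event = rbinom(60, 1, 0.8))
  scan <- scan_cutpoints(coh, grid_probs = 0.5)
  expect_equal(nrow(scan$scan), 1L)
  th <- scan$best_threshold
  direct <- logrank_test(stratify_by_psi(coh, th))
  expect_equal(scan$best_p, direct$p)
  expect_true(scan$multiple_testing_caveat)
})

test_that("cutpoint scan recovers a planted hazard switch", {
  withr::local_seed(56)
  hits <- 0L
  n_seeds <- 10
  for (s in seq_len(n_seeds)) {
    n <- 200
    psi <- runif(n, 0, 20)
    high <- psi >= 10
    time <- rexp(n, ifelse(high, 3, 1) * log(2) / 1000)
    coh <- make_cohort(psi, time = time, event = rep(1L, n))
    grid <- seq(0.1, 0.9, by = 0.05)
    scan <- scan_cutpoints(coh, grid_probs = grid)
    # within one grid step of the planted cut
    qs <- unname(quantile(psi, grid))
    step <- max(diff(sort(qs)))
    if (abs(scan$best_threshold - 10) <= step + 1e-9) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})
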