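#' Stratify patients by a PSI threshold
#'
#' Patients with `psi >= threshold` are labelled `"high"` (the boundary goes
#' to the high stratum) and the rest `"low"`. Patients without a PSI value
#' are excluded and reported.
#'
#' @param cohort Tibble with columns `patient_id`, `time_days`, `event` and
#'   `psi` (percent, 0-100).
#' @param threshold PSI threshold in percent (e.g. 4.07).
#' @param direction Only `"ge_is_high"` is defined: at-or-above-threshold is
#'   the high-inclusion stratum.
#' @return The cohort tibble with a `stratum` column, classed
#'   `"stratified_cohort"`, attribute `threshold`; an empty stratum is an
#'   error stating both counts.
#' @export
stratify_by_psi <- function(cohort, threshold, direction = "ge_is_high") {
  direction <- match.arg(direction, "ge_is_high")
  need <- c("patient_id", "time_days", "event", "psi")
  miss <- setdiff(need, names(cohort))
  if (length(miss) > 0) {
    abort(sprintf("Cohort missing column(s): %s", paste(miss, collapse = ", ")),
      class = "splicescreen_format_error")
  }
  n_na <- sum(is.na(cohort$psi))
  if (n_na > 0) {
    inform(sprintf("Excluded %d patient(s) without a PSI value.", n_na))
    cohort <- cohort[!is.na(cohort$psi), ]
  }
  cohort <- as_tibble(cohort)
  cohort$stratum <- ifelse(cohort$psi >= threshold, "high", "low")
  n_hi <- sum(cohort$stratum == "high")
  n_lo <- sum(cohort$stratum == "low")
  if (n_hi == 0 || n_lo == 0) {
    abort(sprintf("empty stratum: %s (high = %d, low = %d)",
      if (n_hi == 0) "high" else "low", n_hi, n_lo),
      class = "splicescreen_validation_error")
  }
  new_result(cohort, "stratified_cohort",
    threshold = threshold, n_excluded = n_na)
}

#' Kaplan-Meier product-limit survival estimate
#'
#' `S(t) = prod over event times t_i <= t of (1 - d_i / n_i)` with `d_i`
#' deaths and `n_i` at risk at `t_i`; ties at an event time are aggregated
#' into a single `d_i`. The median survival is the smallest time with
#' `S(t) <= 0.5`, `NA` when the curve never reaches 0.5 (never reported as
#' infinity).
#'
#' @param times Positive follow-up times.
#' @param events 0/1 event indicators (1 = death observed).
#' @return A tibble (`time`, `n_risk`, `n_event`, `n_censor`, `surv`) over
#'   the distinct observed times, classed `"km_curve"`, with attributes
#'   `median_survival`, `n` and `n_events`.
#' @export
#' @examples
#' km_estimate(c(1, 2, 3), c(1, 1, 1)) # S = 2/3, 1/3, 0; median 2
km_estimate <- function(times, events) {
  if (length(times) == 0) abort("Empty input.", class = "splicescreen_validation_error")
  stopifnot(length(times) == length(events))
  if (any(is.na(times)) || any(times <= 0)) {
    abort("Times must be positive and non-missing.",
      class = "splicescreen_validation_error")
  }
  if (!all(events %in% c(0, 1))) {
    abort("events must be 0 or 1.", class = "splicescreen_validation_error")
  }
  ut <- sort(unique(times))
  n_risk <- vapply(ut, function(t) sum(times >= t), 0)
  n_event <- vapply(ut, function(t) sum(times == t & events == 1), 0)
  n_censor <- vapply(ut, function(t) sum(times == t & events == 0), 0)
  surv <- cumprod(1 - n_event / n_risk)
  med <- ut[surv <= 0.5][1]
  out <- tibble(time = ut, n_risk = n_risk, n_event = n_event,
    n_censor = n_censor, surv = surv)
  new_result(out, "km_curve",
    median_survival = if (is.na(med)) NA_real_ else med,
    n = length(times), n_events = sum(events))
}

#' Two-group log-rank test
#'
#' At every distinct event time the expected number of events in each stratum
#' is allocated proportionally to its at-risk count, with the exact
#' hypergeometric variance per (possibly tied) time:
#' `V = d * (n1/n) * (1 - n1/n) * (n - d) / (n - 1)`. The statistic
#' `(O1 - E1)^2 / sum(V)` is compared to a chi-square with 1 df. With no
#' events at all the statistic is 0 and p = 1 (with a warning).
#'
#' @param strata A `stratified_cohort`, or any tibble with `time_days`,
#'   `event` and a two-level `stratum` column.
#' @return A `logrank_result` list: `chi_square`, `p`, `df`, and `table`
#'   (per-stratum n, observed and expected events; observed and expected
#'   totals agree).
#' @export
logrank_test <- function(strata) {
  need <- c("time_days", "event", "stratum")
  miss <- setdiff(need, names(strata))
  if (length(miss) > 0) {
    abort(sprintf("Missing column(s): %s", paste(miss, collapse = ", ")),
      class = "splicescreen_format_error")
  }
  lev <- sort(unique(strata$stratum))
  if (length(lev) != 2) {
    abort(sprintf("Need exactly two non-empty strata, found %d.", length(lev)),
      class = "splicescreen_validation_error")
  }
  time <- strata$time_days
  event <- strata$event
  g1 <- strata$stratum == lev[1]
  ev_times <- sort(unique(time[event == 1]))
  if (length(ev_times) == 0) {
    warn("No events in either stratum; log-rank statistic is 0.")
    chi <- 0; p <- 1
    o1 <- e1 <- 0; d_tot <- 0
  } else {
    o1 <- e1 <- v <- 0
    d_tot <- 0
    for (t in ev_times) {
      at <- time >= t
      n <- sum(at)
      n1 <- sum(at & g1)
      d <- sum(time == t & event == 1)
      d1 <- sum(time == t & event == 1 & g1)
      o1 <- o1 + d1
      e1 <- e1 + d * n1 / n
      if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
      d_tot <- d_tot + d
    }
    chi <- if (v > 0) (o1 - e1)^2 / v else 0
    p <- pchisq(chi, df = 1, lower.tail = FALSE)
  }
  tab <- tibble(
    stratum = lev,
    n = c(sum(g1), sum(!g1)),
    observed = c(o1, d_tot - o1),
    expected = c(e1, d_tot - e1)
  )
  structure(
    list(chi_square = chi, p = p, df = 1L, table = tab),
    class = "logrank_result"
  )
}

#' @export
print.logrank_result <- function(x, ...) {
  cat("Two-group log-rank test\n")
  print(x$table)
  cat(sprintf("chi-square = %.4g on %d df, p = %.4g\n", x$chi_square, x$df, x$p))
  invisible(x)
}

#' Scan PSI cutpoints for survival separation
#'
#' Evaluates the log-rank test at every candidate threshold taken from the
#' quantiles of the observed PSI distribution, keeping only thresholds that
#' leave at least `min_group_frac` of the patients in each stratum, and
#' returns the threshold minimising the log-rank p-value. Because the best
#' p-value is selected over many looks, it is *not* an honest significance
#' level; the result carries `multiple_testing_caveat = TRUE` to make that
#' explicit.
#'
#' @param cohort Tibble with `patient_id`, `time_days`, `event`, `psi`.
#' @param grid_probs Quantile probabilities defining the candidate
#'   thresholds.
#' @param min_group_frac Minimum fraction of patients per stratum for a
#'   threshold to be admissible.
#' @return A list (`best_threshold`, `best_p`, `scan` tibble with one row per
#'   admissible threshold, `multiple_testing_caveat`), classed
#'   `"cutpoint_scan"`. Constant PSI (no admissible threshold) is an error.
#' @export
scan_cutpoints <- function(cohort, grid_probs = seq(0.1, 0.9, by = 0.05),
                           min_group_frac = 0.1) {
  psi <- cohort$psi[!is.na(cohort$psi)]
  thresholds <- unique(unname(quantile(psi, grid_probs)))
  n <- length(psi)
  min_n <- max(1, ceiling(min_group_frac * n))
  rows <- purrr::map_dfr(thresholds, function(th) {
    n_hi <- sum(psi >= th); n_lo <- n - n_hi
    if (n_hi < min_n || n_lo < min_n) return(NULL)
    strat <- stratify_by_psi(cohort, th)
    lr <- logrank_test(strat)
    tibble(threshold = th, n_high = n_hi, n_low = n_lo,
      chi_square = lr$chi_square, p = lr$p)
  })
  if (nrow(rows) == 0) {
    abort("No admissible threshold (PSI nearly constant or groups too small).",
      class = "splicescreen_validation_error")
  }
  best <- rows[order(rows$p, rows$threshold), ][1, ]
  structure(
    list(best_threshold = best$threshold, best_p = best$p, scan = rows,
      multiple_testing_caveat = TRUE),
    class = "cutpoint_scan"
  )
}
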