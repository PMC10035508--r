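# broom-style tidiers for the package's result objects.

#' @describeIn km_estimate `tidy()` returns the curve as a plain tibble.
#' @param x A `km_curve`.
#' @param ... Unused.
#' @method tidy km_curve
#' @export
tidy.km_curve <- function(x, ...) {
  out <- x
  attributes(out)[c("median_survival", "n", "n_events")] <- NULL
  class(out) <- c("tbl_df", "tbl", "data.frame")
  out
}

#' @describeIn km_estimate `glance()` returns n, events and median survival.
#' @method glance km_curve
#' @export
glance.km_curve <- function(x, ...) {
  tibble(n = attr(x, "n"), events = attr(x, "n_events"),
    median_survival = attr(x, "median_survival"))
}

#' Median survival of a Kaplan-Meier curve
#' @param curve A `km_curve`.
#' @return Smallest time with `S(t) <= 0.5`, or `NA` if never reached.
#' @export
km_median <- function(curve) {
  stopifnot(inherits(curve, "km_curve"))
  attr(curve, "median_survival")
}

#' @describeIn logrank_test `tidy()` returns the per-stratum table.
#' @param x A `logrank_result`.
#' @param ... Unused.
#' @method tidy logrank_result
#' @export
tidy.logrank_result <- function(x, ...) x$table

#' @describeIn logrank_test `glance()` returns the statistic and p-value.
#' @method glance logrank_result
#' @export
glance.logrank_result <- function(x, ...) {
  tibble(chi_square = x$chi_square, df = x$df, p = x$p)
}

#' @describeIn fit_kd `tidy()` returns a one-row tibble of the fit.
#' @param x A `kd_fit`.
#' @param ... Unused.
#' @method tidy kd_fit
#' @export
tidy.kd_fit <- function(x, ...) {
  tibble(probe = x$probe, kd_hat = x$kd_hat, sd = x$sd,
    censored = x$censored, kd_lower = x$kd_lower,
    n_points = x$n_points, residual_sse = x$residual_sse,
    converged = x$converged)
}

#' @describeIn fit_kd `glance()` is an alias for `tidy()` (one-row summary).
#' @method glance kd_fit
#' @export
glance.kd_fit <- function(x, ...) tidy.kd_fit(x, ...)

#' @describeIn correlate_rbp_usage `tidy()` strips the class, returning a
#'   plain tibble of the ranked screen.
#' @param x A `screen_result`.
#' @param ... Unused.
#' @method tidy screen_result
#' @export
tidy.screen_result <- function(x, ...) {
  out <- x
  attributes(out)[c("junction", "log1p", "untestable")] <- NULL
  class(out) <- c("tbl_df", "tbl", "data.frame")
  out
}

#' @describeIn correlate_rbp_usage `glance()` summarises tested and
#'   untestable counts.
#' @method glance screen_result
#' @export
glance.screen_result <- function(x, ...) {
  tibble(n_tested = nrow(x),
    n_untestable = nrow(attr(x, "untestable") %||% tibble()),
    top_rbp = x$rbp[1], top_r = x$r[1])
}

#' @describeIn scan_cutpoints `tidy()` returns the full scan table.
#' @param x A `cutpoint_scan`.
#' @param ... Unused.
#' @method tidy cutpoint_scan
#' @export
tidy.cutpoint_scan <- function(x, ...) x$scan

#' @describeIn scan_cutpoints `glance()` returns the selected threshold (with
#'   its multiple-testing caveat flag).
#' @method glance cutpoint_scan
#' @export
glance.cutpoint_scan <- function(x, ...) {
  tibble(best_threshold = x$best_threshold, best_p = x$best_p,
    n_thresholds = nrow(x$scan),
    multiple_testing_caveat = x$multiple_testing_caveat)
}
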