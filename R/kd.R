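#' Single-site equilibrium binding isotherm
#'
#' Fraction of RNA bound at protein concentration `conc` with dissociation
#' constant `kd`: `f = 1 / (1 + kd / conc)`, with `f(0) = 0` by continuity.
#' Strictly increasing in concentration and strictly decreasing in `kd`;
#' `f = 0.5` exactly at `conc = kd` (half-saturation).
#'
#' @param conc Protein concentration(s), nmol/L; non-negative.
#' @param kd Dissociation constant, nmol/L; must be positive.
#' @return Bound fraction(s) in `[0, 1)`.
#' @export
#' @examples
#' isotherm(100, kd = 100) # 0.5
isotherm <- function(conc, kd) {
  if (!is.numeric(kd) || length(kd) != 1 || is.na(kd) || kd <= 0) {
    abort("kd must be a single positive number (nmol/L).",
      class = "splicescreen_validation_error")
  }
  if (any(conc < 0, na.rm = TRUE)) {
    abort("Concentrations must be >= 0.", class = "splicescreen_validation_error")
  }
  ifelse(conc == 0, 0, 1 / (1 + kd / conc))
}

kd_sse <- function(log_kd, conc, bound, plateau = 1) {
  sum((bound - plateau * isotherm(conc, exp(log_kd)))^2)
}

# Core 1-D least-squares fit over log-kd; returns list(kd, sse, converged).
fit_kd_core <- function(conc, bound, free_plateau = FALSE) {
  pos <- conc > 0
  lo <- log(min(conc[pos])) - log(1e4)
  hi <- log(max(conc)) + log(1e4)
  if (free_plateau) {
    obj <- function(par) kd_sse(par[1], conc, bound, plateau = par[2])
    # start at the concentration nearest half-saturation, full amplitude
    start <- c(log(conc[pos][which.min(abs(bound[pos] - 0.5))]), 1)
    op <- stats::optim(start, obj, method = "L-BFGS-B",
      lower = c(lo, 1e-3), upper = c(hi, 1.5))
    list(kd = exp(op$par[1]), plateau = op$par[2], sse = op$value,
      converged = op$convergence == 0 &&
        op$par[1] > lo + 1e-6 && op$par[1] < hi - 1e-6)
  } else {
    op <- optimize(kd_sse, c(lo, hi), conc = conc, bound = bound, tol = 1e-10)
    list(kd = exp(op$minimum), plateau = 1, sse = op$objective,
      converged = op$minimum > lo + 1e-4 && op$minimum < hi - 1e-4)
  }
}

#' Fit a dissociation constant to EMSA titration data
#'
#' Least-squares fit of the single-site isotherm `1 / (1 + Kd / conc)` to
#' (concentration, bound fraction) points, parameterised in `log(Kd)` so the
#' estimate is positive by construction. Bound fractions outside `[0, 1]`
#' (gel quantification noise) are clipped with a report. The amplitude is
#' fixed at 1 (fully bindable RNA); `free_plateau = TRUE` frees it for
#' sensitivity analysis.
#'
#' When no appreciable binding is observed (maximum bound fraction below
#' `unbound_threshold`), the probe is declared *unbound*: no numeric Kd is
#' reported, only the censored lower bound `Kd > max(conc)`.
#'
#' The uncertainty is the standard deviation of per-replicate fits when at
#' least 3 replicates are present (`sd_method = "auto"`), otherwise a seeded
#' nonparametric bootstrap over points (`n_boot` resamples).
#'
#' @param data Tibble with columns `conc` (nmol/L) and `bound_frac`, and
#'   optionally `replicate` and `probe` (a single probe only).
#' @param free_plateau Free the saturation amplitude (default fixed at 1).
#' @param sd_method `"auto"`, `"replicate"` or `"bootstrap"`.
#' @param n_boot Bootstrap resamples (default 200).
#' @param boot_seed Seed for the bootstrap resampling.
#' @param unbound_threshold Maximum bound fraction below which the probe is
#'   declared unbound (default 0.2).
#' @return A `kd_fit` object: `kd_hat`, `sd`, `n_points`, `residual_sse`,
#'   `converged`, `censored`, `kd_lower` (censoring bound), `plateau`,
#'   `sd_method`, and the (clipped) data.
#' @export
fit_kd <- function(data, free_plateau = FALSE,
                   sd_method = c("auto", "replicate", "bootstrap"),
                   n_boot = 200, boot_seed = 1L, unbound_threshold = 0.2) {
  sd_method <- match.arg(sd_method)
  stopifnot(is.data.frame(data), all(c("conc", "bound_frac") %in% names(data)))
  if ("probe" %in% names(data) && length(unique(data$probe)) > 1) {
    abort("fit_kd() fits one probe; split the table by probe first.",
      class = "splicescreen_validation_error")
  }
  conc <- as.numeric(data$conc)
  bound <- as.numeric(data$bound_frac)
  if (any(is.na(conc)) || any(conc < 0)) {
    abort("Concentrations must be non-negative.",
      class = "splicescreen_validation_error")
  }
  if (length(unique(conc[conc > 0])) < 3) {
    abort("Need at least 3 distinct positive concentrations.",
      class = "splicescreen_validation_error")
  }
  n_clipped <- sum(bound < 0 | bound > 1, na.rm = TRUE)
  if (n_clipped > 0) {
    inform(sprintf("Clipped %d bound fraction(s) to [0, 1].", n_clipped))
    bound <- pmin(pmax(bound, 0), 1)
  }
  probe <- if ("probe" %in% names(data)) data$probe[1] else NA_character_

  if (max(bound, na.rm = TRUE) < unbound_threshold) {
    fit <- list(kd_hat = NA_real_, sd = NA_real_, n_points = length(conc),
      residual_sse = NA_real_, converged = FALSE, censored = TRUE,
      kd_lower = max(conc), plateau = NA_real_, sd_method = NA_character_,
      probe = probe, n_clipped = n_clipped,
      data = tibble(conc = conc, bound_frac = bound))
    class(fit) <- "kd_fit"
    return(fit)
  }

  core <- fit_kd_core(conc, bound, free_plateau)
  if (!core$converged) {
    warn("Kd fit did not converge to an interior optimum.")
  }

  reps <- if ("replicate" %in% names(data)) data$replicate else NULL
  use_reps <- switch(sd_method,
    replicate = TRUE,
    bootstrap = FALSE,
    auto = !is.null(reps) && length(unique(reps)) >= 3
  )
  if (use_reps && (is.null(reps) || length(unique(reps)) < 2)) {
    abort("Replicate-based SD requested but no replicate structure present.",
      class = "splicescreen_validation_error")
  }
  if (use_reps) {
    kds <- vapply(split(seq_along(conc), reps), function(idx) {
      if (length(unique(conc[idx][conc[idx] > 0])) < 3) return(NA_real_)
      fit_kd_core(conc[idx], bound[idx], free_plateau)$kd
    }, 0)
    sd_hat <- sd(kds, na.rm = TRUE)
    sd_used <- "replicate"
  } else {
    kds <- withr::with_seed(boot_seed, {
      vapply(seq_len(n_boot), function(b) {
        idx <- sample.int(length(conc), replace = TRUE)
        if (length(unique(conc[idx][conc[idx] > 0])) < 3) return(NA_real_)
        fit_kd_core(conc[idx], bound[idx], free_plateau)$kd
      }, 0)
    })
    sd_hat <- sd(kds, na.rm = TRUE)
    sd_used <- "bootstrap"
  }

  fit <- list(kd_hat = core$kd, sd = sd_hat, n_points = length(conc),
    residual_sse = core$sse, converged = core$converged, censored = FALSE,
    kd_lower = NA_real_, plateau = core$plateau, sd_method = sd_used,
    probe = probe, n_clipped = n_clipped,
    data = tibble(conc = conc, bound_frac = bound))
  class(fit) <- "kd_fit"
  fit
}

#' @export
print.kd_fit <- function(x, ...) {
  if (x$censored) {
    cat(sprintf("Kd fit (%s): unbound; Kd > %.4g nmol/L (censored), %d points\n",
      x$probe %||% "probe", x$kd_lower, x$n_points))
  } else {
    cat(sprintf("Kd fit (%s): Kd = %.4g nmol/L (SD %.3g, %s), %d points, SSE %.3g\n",
      x$probe %||% "probe", x$kd_hat, x$sd, x$sd_method, x$n_points,
      x$residual_sse))
  }
  invisible(x)
}

#' Compare two fitted dissociation constants
#'
#' Reports `fold = kd_b / kd_a` with a delta-method confidence interval on
#' the log scale. When fit `b` is censored (unbound probe), the fold change
#' is reported as a lower bound `>= kd_lower_b / kd_a`.
#'
#' @param fit_a,fit_b `kd_fit` objects; `fit_a` must be a converged numeric
#'   fit.
#' @param conf_level Confidence level for the interval (default 0.95).
#' @return A tibble (`fold`, `conf_low`, `conf_high`, `censored`,
#'   `kd_a`, `kd_b`), classed `"kd_comparison"`; for a censored `fit_b`,
#'   `fold` holds the lower bound and `censored` is `TRUE`.
#' @export
compare_kd <- function(fit_a, fit_b, conf_level = 0.95) {
  stopifnot(inherits(fit_a, "kd_fit"), inherits(fit_b, "kd_fit"))
  if (fit_a$censored) {
    abort("Reference fit is censored (unbound); no fold change defined.",
      class = "splicescreen_validation_error")
  }
  if (!fit_a$converged) {
    abort("Reference fit did not converge.", class = "splicescreen_validation_error")
  }
  if (fit_b$censored) {
    out <- tibble(fold = fit_b$kd_lower / fit_a$kd_hat,
      conf_low = NA_real_, conf_high = NA_real_, censored = TRUE,
      kd_a = fit_a$kd_hat, kd_b = NA_real_)
    return(new_result(out, "kd_comparison"))
  }
  fold <- fit_b$kd_hat / fit_a$kd_hat
  se_log <- sqrt((fit_a$sd / fit_a$kd_hat)^2 + (fit_b$sd / fit_b$kd_hat)^2)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  out <- tibble(
    fold = fold,
    conf_low = fold * exp(-z * se_log),
    conf_high = fold * exp(z * se_log),
    censored = FALSE,
    kd_a = fit_a$kd_hat, kd_b = fit_b$kd_hat
  )
  new_result(out, "kd_comparison")
}
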