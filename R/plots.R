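# ggplot2 displays for the package's result types.

#' Plot a Kaplan-Meier curve
#' @param object A `km_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot km_curve
#' @export
autoplot.km_curve <- function(object, ...) {
  df <- dplyr::bind_rows(
    tibble(time = 0, surv = 1),
    tidy(object)[, c("time", "surv")]
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$surv)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time (days)", y = "Survival probability") +
    ggplot2::theme_minimal()
}

#' Kaplan-Meier curves by PSI stratum with log-rank p-value
#'
#' @param strata A `stratified_cohort` (from [stratify_by_psi()]).
#' @return A ggplot of both strata's product-limit curves, annotated with the
#'   log-rank p-value.
#' @export
plot_km_strata <- function(strata) {
  lr <- logrank_test(strata)
  df <- purrr::map_dfr(split(strata, strata$stratum), function(d) {
    km <- km_estimate(d$time_days, d$event)
    dplyr::bind_rows(tibble(time = 0, surv = 1), tidy(km)[, c("time", "surv")]) |>
      dplyr::mutate(stratum = d$stratum[1])
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$surv,
      colour = .data$stratum)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time (days)", y = "Survival probability",
      colour = "PSI stratum",
      subtitle = sprintf("log-rank p = %.3g", lr$p)) +
    ggplot2::theme_minimal()
}

#' Plot a regulator screen as a signed correlation bar chart
#' @param object A `screen_result`.
#' @param top Show the `top` ranked RBPs (default 10).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot screen_result
#' @export
autoplot.screen_result <- function(object, top = 10, ...) {
  df <- tidy(object)[seq_len(min(top, nrow(object))), ]
  df$rbp <- factor(df$rbp, levels = rev(df$rbp))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$r, y = .data$rbp,
      fill = .data$sign)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Pearson r (expression vs junction usage)", y = NULL,
      fill = "Sign") +
    ggplot2::theme_minimal()
}

#' Plot a Kd fit: titration points and fitted isotherm
#' @param object A converged `kd_fit`.
#' @param ... Unused.
#' @return A ggplot (log10 concentration axis).
#' @method autoplot kd_fit
#' @export
autoplot.kd_fit <- function(object, ...) {
  pts <- object$data[object$data$conc > 0, ]
  p <- ggplot2::ggplot(pts, ggplot2::aes(x = .data$conc, y = .data$bound_frac)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "[protein] (nmol/L)", y = "Bound fraction") +
    ggplot2::theme_minimal()
  if (!object$censored) {
    grid <- tibble(conc = exp(seq(log(min(pts$conc)), log(max(pts$conc)),
      length.out = 200)))
    grid$fit <- (object$plateau %||% 1) * isotherm(grid$conc, object$kd_hat)
    p <- p + ggplot2::geom_line(data = grid,
        ggplot2::aes(x = .data$conc, y = .data$fit)) +
      ggplot2::labs(subtitle = sprintf("Kd = %.3g nmol/L (SD %.2g)",
        object$kd_hat, object$sd))
  } else {
    p <- p + ggplot2::labs(subtitle = sprintf("unbound (Kd > %.3g nmol/L)",
      object$kd_lower))
  }
  p
}

#' Volcano plot of a differential-expression result
#'
#' `log2fc` against `-log10(p_adj)`, prognostic markers coloured, with the
#' significance threshold drawn as a dashed line.
#'
#' @param de A `de_result`, usually after [annotate_prognostic()].
#' @param alpha Adjusted-p significance threshold to draw (default 0.05).
#' @return A ggplot.
#' @export
plot_volcano <- function(de, alpha = 0.05) {
  stopifnot(inherits(de, "de_result"))
  df <- de[!is.na(de$p_adj), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2fc,
      y = -log10(.data$p_adj), colour = .data$prognosis)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed",
      colour = "red") +
    ggplot2::scale_colour_manual(values = c(favorable = "blue",
      unfavorable = "red", none = "grey60")) +
    ggplot2::labs(x = "log2 fold change (high vs low PSI)",
      y = "-log10 adjusted p", colour = "Prognostic marker") +
    ggplot2::theme_minimal()
}

#' @rdname plot_volcano
#' @param object A `de_result`.
#' @param ... Passed to [plot_volcano()].
#' @method autoplot de_result
#' @export
autoplot.de_result <- function(object, ...) plot_volcano(object, ...)
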