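#' Correlate RBP expression with junction usage across samples
#'
#' For each RNA-binding protein (one row of `rbp_expr`) the Pearson
#' correlation coefficient between its normalized expression and the target
#' junction's usage is computed over pairwise-complete samples, with the
#' two-sided p-value from `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2`
#' degrees of freedom. Correlation is computed on individual samples (not
#' tissue means) and on expression as-is; set `log1p = TRUE` to correlate on
#' `log1p`-transformed expression instead.
#'
#' RBPs with fewer than 3 complete pairs or zero variance are reported as
#' untestable (attribute `untestable`), not ranked.
#'
#' @param rbp_expr Expression tibble restricted to the RBP list (`gene`
#'   column plus sample columns).
#' @param usage Usage for one junction: a `usage_table` (then `junction` must
#'   name the junction), a tibble with `sample_id` and `usage` columns, or a
#'   named numeric vector.
#' @param junction Junction id to extract when `usage` is a full usage table.
#' @param log1p Correlate on `log1p(expression)` instead of raw values.
#' @return A tibble (`rbp`, `r`, `p`, `n`, `sign`, `rank`) sorted by rank
#'   (decreasing `|r|`; ties by smaller p, then symbol), classed
#'   `"screen_result"`.
#' @export
correlate_rbp_usage <- function(rbp_expr, usage, junction = NULL, log1p = FALSE) {
  u <- usage_vector(usage, junction)
  scols <- intersect(sample_cols(rbp_expr), names(u))
  if (length(scols) < 3) {
    abort("Fewer than 3 samples shared between expression and usage.",
      class = "splicescreen_validation_error")
  }
  u <- u[scols]
  rows <- purrr::map(seq_len(nrow(rbp_expr)), function(i) {
    x <- as.numeric(unlist(rbp_expr[i, scols]))
    if (log1p) x <- log1p(x)
    ok <- !is.na(x) & !is.na(u)
    n <- sum(ok)
    if (n < 3) {
      return(list(rbp = rbp_expr$gene[i], status = "fewer than 3 complete pairs"))
    }
    if (stats::var(x[ok]) == 0 || stats::var(u[ok]) == 0) {
      return(list(rbp = rbp_expr$gene[i], status = "zero variance"))
    }
    ct <- cor.test(x[ok], u[ok], method = "pearson", alternative = "two.sided")
    list(rbp = rbp_expr$gene[i], r = unname(ct$estimate),
      p = max(ct$p.value, .Machine$double.xmin), n = n)
  })
  untestable <- purrr::map_dfr(
    purrr::keep(rows, ~ !is.null(.x$status)),
    ~ tibble(rbp = .x$rbp, reason = .x$status))
  tested <- purrr::map_dfr(
    purrr::keep(rows, ~ is.null(.x$status)),
    ~ tibble(rbp = .x$rbp, r = .x$r, p = .x$p, n = .x$n))
  if (nrow(tested) == 0) {
    abort("No testable RBP (all zero-variance or too few pairs).",
      class = "splicescreen_validation_error")
  }
  ord <- order(-abs(tested$r), tested$p, tested$rbp)
  tested <- tested[ord, ]
  tested$sign <- ifelse(tested$r >= 0, "+", "-")
  tested$rank <- seq_len(nrow(tested))
  new_result(tested, "screen_result",
    junction = junction, log1p = log1p, untestable = untestable)
}

usage_vector <- function(usage, junction = NULL) {
  if (is.numeric(usage) && !is.null(names(usage))) return(usage)
  stopifnot(is.data.frame(usage))
  if (inherits(usage, "usage_table") || "junction_id" %in% names(usage)) {
    if (length(unique(usage$junction_id)) > 1) {
      if (is.null(junction)) {
        abort("Multiple junctions in usage table: name one via `junction`.",
          class = "splicescreen_validation_error")
      }
      usage <- usage[usage$junction_id == junction, ]
      if (nrow(usage) == 0) {
        abort(sprintf("Junction '%s' not in usage table.", junction),
          class = "splicescreen_validation_error")
      }
    }
  }
  setNames(usage$usage, usage$sample_id)
}

#' Top-k candidate regulators by correlation strength
#'
#' Keeps the `k` RBPs with the largest `|r|`; ties are broken by smaller
#' p-value and then by gene symbol so the selection is deterministic.
#'
#' @param result A `screen_result`.
#' @param k Number of candidates to keep (default 10).
#' @return The top-`k` rows (all rows, with a warning, when `k` exceeds the
#'   number of tested RBPs), still a `screen_result`.
#' @export
rank_candidates <- function(result, k = 10) {
  stopifnot(inherits(result, "screen_result"))
  if (k < 1) abort("k must be >= 1.", class = "splicescreen_validation_error")
  if (k > nrow(result)) {
    warn(sprintf("k = %d exceeds the %d tested RBPs; returning all.", k, nrow(result)))
    k <- nrow(result)
  }
  out <- result[seq_len(k), ]
  attributes(out)[c("junction", "log1p", "untestable")] <-
    attributes(result)[c("junction", "log1p", "untestable")]
  class(out) <- class(result)
  out
}

#' Tumor sign-concordance filter for candidate regulators
#'
#' A candidate whose expression is negatively correlated with exon usage in
#' the multi-tissue panel is a plausible repressor only if its expression is
#' also *lower* in high-PSI tumors (and symmetrically, a positively
#' correlated candidate must be *higher* in high-PSI tumors). Differential
#' expression between the tumor groups is assessed with a two-sided Wilcoxon
#' rank-sum test at level `alpha`; direction is the sign of the median
#' difference. A candidate significant in the direction opposite to its
#' correlation sign — or not significant at all — fails the filter.
#'
#' @param candidates A `screen_result` (typically [rank_candidates()] output).
#' @param tumor_expr Tumor expression tibble containing the candidate genes.
#' @param groups Stratum labels for the tumor samples: tibble
#'   (`sample_id`, `stratum`) with values `"high"`/`"low"`, or a named
#'   character vector.
#' @param alpha Significance level for the Wilcoxon test (default 0.05).
#' @return Tibble (`rbp`, `correlation_sign`, `tumor_de_sign`, `tumor_p`,
#'   `concordant`), classed `"concordance_result"`.
#' @export
concordance_filter <- function(candidates, tumor_expr, groups, alpha = 0.05) {
  stopifnot(inherits(candidates, "screen_result"))
  g <- as_named_vector(groups, "stratum", "sample_id")
  if (!all(g %in% c("high", "low"))) {
    abort("Group labels must be 'high' or 'low'.",
      class = "splicescreen_validation_error")
  }
  scols <- intersect(sample_cols(tumor_expr), names(g))
  hi <- scols[g[scols] == "high"]
  lo <- scols[g[scols] == "low"]
  if (length(hi) < 2 || length(lo) < 2) {
    abort(sprintf("Each tumor group needs >= 2 samples (high = %d, low = %d).",
      length(hi), length(lo)), class = "splicescreen_validation_error")
  }
  missing <- setdiff(candidates$rbp, tumor_expr$gene)
  if (length(missing) > 0) {
    warn(sprintf("Candidate(s) absent from tumor expression skipped: %s",
      paste(missing, collapse = ", ")))
  }
  out <- purrr::map_dfr(seq_len(nrow(candidates)), function(i) {
    rbp <- candidates$rbp[i]
    if (!rbp %in% tumor_expr$gene) return(NULL)
    xh <- as.numeric(unlist(tumor_expr[tumor_expr$gene == rbp, hi]))
    xl <- as.numeric(unlist(tumor_expr[tumor_expr$gene == rbp, lo]))
    wt <- suppressWarnings(wilcox.test(xh, xl, alternative = "two.sided"))
    de_sign <- if (wt$p.value >= alpha) "ns"
      else if (median(xh) > median(xl)) "higher_in_highPSI"
      else "lower_in_highPSI"
    corr_sign <- candidates$sign[i]
    tibble(
      rbp = rbp,
      correlation_sign = corr_sign,
      tumor_de_sign = de_sign,
      tumor_p = wt$p.value,
      concordant = (corr_sign == "-" && de_sign == "lower_in_highPSI") ||
        (corr_sign == "+" && de_sign == "higher_in_highPSI")
    )
  })
  new_result(out, "concordance_result", alpha = alpha)
}
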