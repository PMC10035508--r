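#' Per-sample read-depth normalization factors
#'
#' For every sample `s` the total read count `Ts` is the column sum of the
#' matrix; the median read depth `Mrd` is the median of the retained totals,
#' and the normalization factor is `Ns = Mrd / Ts`, so that multiplying a
#' sample's counts by `Ns` equalises sequencing depth across samples. Samples
#' with a zero total are excluded from the factors (and from `Mrd`) and
#' reported via the `excluded` attribute.
#'
#' @param counts A `junction_counts` or `expression_matrix` tibble (columns
#'   `junction_id`/`gene` plus one numeric column per sample).
#' @return A tibble with columns `sample_id`, `total_reads`, `norm_factor`,
#'   classed `"depth_factors"`, with attributes `mrd` (the median read depth)
#'   and `excluded` (zero-total samples).
#' @export
#' @examples
#' x <- tibble::tibble(gene = c("A", "B"), s1 = c(60, 40), s2 = c(150, 50))
#' compute_depth_factors(x)
compute_depth_factors <- function(counts) {
  scols <- sample_cols(counts)
  if (length(scols) == 0) abort("No sample columns.", class = "splicescreen_format_error")
  totals <- colSums(as.matrix(counts[, scols, drop = FALSE]))
  excluded <- names(totals)[totals == 0]
  totals <- totals[totals > 0]
  if (length(totals) == 0) {
    abort("no usable samples: all column totals are zero.",
      class = "splicescreen_validation_error")
  }
  if (length(excluded) > 0) {
    warn(sprintf("Excluded %d zero-total sample(s): %s", length(excluded),
      paste(utils::head(excluded, 5), collapse = ", ")))
  }
  mrd <- median(totals)
  out <- tibble(
    sample_id = names(totals),
    total_reads = unname(totals),
    norm_factor = unname(mrd / totals)
  )
  new_result(out, "depth_factors", mrd = mrd, excluded = excluded)
}

#' Depth-normalize an expression (or count) matrix
#'
#' Computes `Egs = raw[g, s] * Ns[s]`. When the factors derive from the same
#' matrix, every normalized column total equals the median read depth `Mrd`
#' (depth conservation).
#'
#' @param raw Expression tibble (`gene` column plus sample columns).
#' @param factors Result of [compute_depth_factors()]; must cover every sample
#'   column of `raw`.
#' @return The normalized tibble, classed `"expression_matrix"` with
#'   `normalized = TRUE`.
#' @export
normalize_expression <- function(raw, factors) {
  scols <- sample_cols(raw)
  ns <- setNames(factors$norm_factor, factors$sample_id)
  miss <- setdiff(scols, names(ns))
  if (length(miss) > 0) {
    abort(sprintf("No normalization factor for sample(s): %s",
      paste(utils::head(miss, 5), collapse = ", ")),
      class = "splicescreen_validation_error")
  }
  out <- raw
  for (sc in scols) out[[sc]] <- raw[[sc]] * ns[[sc]]
  attr(out, "normalized") <- TRUE
  attr(out, "unit") <- paste0(attr(raw, "unit") %||% "counts", " (depth-normalized)")
  if (!inherits(out, "expression_matrix")) class(out) <- c("expression_matrix", class(out))
  out
}

#' Select tissues and samples expressing a gene
#'
#' A tissue is called expressing when the chosen per-tissue statistic (median
#' by default, robust to outlier samples) of the gene's normalized expression
#' over that tissue's samples is at or above `threshold`. The selected samples
#' are all samples of the expressing tissues present in the matrix.
#'
#' @param expr Expression tibble (ideally depth-normalized).
#' @param attrs Sample attributes (`sample_id`, `tissue`).
#' @param gene Gene symbol to test.
#' @param threshold Expression threshold, in the matrix's units.
#' @param statistic Per-tissue summary: `"median"` (default) or `"mean"`.
#' @return A tibble with one row per tissue (`tissue`, `n_samples`,
#'   `expr_stat`, `expressing`), classed `"tissue_selection"`, with attributes
#'   `gene`, `threshold`, `statistic` and `samples` (the selected sample ids).
#' @export
select_expressing <- function(expr, attrs, gene, threshold,
                              statistic = c("median", "mean")) {
  statistic <- match.arg(statistic)
  if (!gene %in% expr$gene) {
    abort(sprintf("Gene '%s' not present in the expression matrix.", gene),
      class = "splicescreen_validation_error")
  }
  scols <- sample_cols(expr)
  common <- intersect(scols, attrs$sample_id)
  unmatched <- setdiff(scols, attrs$sample_id)
  if (length(unmatched) > 0) {
    inform(sprintf("%d sample(s) without attributes ignored.", length(unmatched)))
  }
  vals <- unlist(expr[expr$gene == gene, common, drop = FALSE])
  tis <- setNames(attrs$tissue, attrs$sample_id)[common]
  fun <- if (statistic == "median") median else mean
  per_tissue <- tibble(sample_id = common, tissue = unname(tis), value = unname(vals)) |>
    dplyr::group_by(.data$tissue) |>
    dplyr::summarise(n_samples = dplyr::n(), expr_stat = fun(.data$value),
      .groups = "drop") |>
    dplyr::mutate(expressing = .data$expr_stat >= threshold)
  samples <- common[tis %in% per_tissue$tissue[per_tissue$expressing]]
  if (length(samples) == 0) {
    warn(sprintf("No tissue reaches the '%s' expression threshold %g for %s.",
      statistic, threshold, gene))
  }
  new_result(per_tissue, "tissue_selection",
    gene = gene, threshold = threshold, statistic = statistic, samples = samples)
}

#' Sample ids selected by [select_expressing()]
#' @param selection A `tissue_selection` object.
#' @return Character vector of selected sample ids.
#' @export
expressing_samples <- function(selection) {
  stopifnot(inherits(selection, "tissue_selection"))
  attr(selection, "samples")
}
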