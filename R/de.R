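#' Gene-wise Wilcoxon rank-sum differential expression
#'
#' Compares the two PSI-defined tumor groups gene by gene with a two-sided
#' Wilcoxon rank-sum test (exact for small groups without ties, normal
#' approximation with tie correction otherwise), Benjamini-Hochberg
#' adjustment across testable genes, and a pseudocount fold change
#' `log2fc = log2((mean(high) + 1) / (mean(low) + 1))`. Genes with identical
#' values in every sample are untestable: their statistic and p-values are
#' `NA` and they are excluded from the adjustment.
#'
#' @param expr Expression tibble (`gene` plus sample columns), typically
#'   depth-normalized.
#' @param groups Tibble (`sample_id`, `stratum` in `"high"`/`"low"`) or a
#'   named character vector; every expression sample must be labelled.
#' @return Tibble (`gene`, `stat`, `p`, `p_adj`, `log2fc`, `prognosis`)
#'   classed `"de_result"`; `prognosis` starts at `"none"` and is filled by
#'   [annotate_prognostic()].
#' @export
wilcoxon_de <- function(expr, groups) {
  g <- as_named_vector(groups, "stratum", "sample_id")
  scols <- sample_cols(expr)
  miss <- setdiff(scols, names(g))
  if (length(miss) > 0) {
    abort(sprintf("No group label for sample(s): %s",
      paste(utils::head(miss, 5), collapse = ", ")),
      class = "splicescreen_validation_error")
  }
  if (!all(g[scols] %in% c("high", "low"))) {
    abort("Group labels must be 'high' or 'low'.",
      class = "splicescreen_validation_error")
  }
  hi <- scols[g[scols] == "high"]
  lo <- scols[g[scols] == "low"]
  if (length(hi) < 2 || length(lo) < 2) {
    abort("Each group needs at least 2 samples.",
      class = "splicescreen_validation_error")
  }
  m <- as.matrix(expr[, scols, drop = FALSE])
  res <- purrr::map_dfr(seq_len(nrow(expr)), function(i) {
    xh <- m[i, hi]; xl <- m[i, lo]
    l2fc <- log2((mean(xh) + 1) / (mean(xl) + 1))
    if (length(unique(c(xh, xl))) == 1) {
      return(tibble(gene = expr$gene[i], stat = NA_real_, p = NA_real_,
        log2fc = l2fc))
    }
    wt <- suppressWarnings(wilcox.test(xh, xl, alternative = "two.sided"))
    tibble(gene = expr$gene[i], stat = unname(wt$statistic), p = wt$p.value,
      log2fc = l2fc)
  })
  res$p_adj <- NA_real_
  testable <- !is.na(res$p)
  res$p_adj[testable] <- bh_adjust(res$p[testable])
  res$prognosis <- "none"
  res <- res[, c("gene", "stat", "p", "p_adj", "log2fc", "prognosis")]
  new_result(res, "de_result",
    n_high = length(hi), n_low = length(lo),
    method = "Wilcoxon rank-sum (two-sided), BH adjustment")
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard FDR step-up: sort ascending, multiply `p_(i)` by `m / i`, enforce
#' monotonicity from the largest rank down, cap at 1, restore input order.
#'
#' @param pvals Numeric p-values in (0, 1].
#' @return Adjusted p-values, elementwise >= the input and <= 1.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04)) # all 0.04
bh_adjust <- function(pvals) {
  if (length(pvals) == 0) return(numeric(0))
  if (any(is.na(pvals)) || any(pvals <= 0) || any(pvals > 1)) {
    abort("p-values must lie in (0, 1].", class = "splicescreen_validation_error")
  }
  p.adjust(pvals, method = "BH")
}

#' Hypergeometric gene-set enrichment ("classic" test)
#'
#' For each set, with `N` universe genes, `K` of them in the set, `n`
#' differential genes and `k` differential genes in the set, the upper-tail
#' hypergeometric probability `P(X >= k)` is the enrichment p-value and
#' `(k/n) / (K/N)` the fold enrichment (observed over expected). This is the
#' classic over-representation test: no term-graph decorrelation is applied,
#' and the output is labelled accordingly. P-values are BH-adjusted across
#' sets.
#'
#' @param de_genes Character vector of differential genes; must be a subset
#'   of `universe`.
#' @param sets Named list of character vectors, or a tibble
#'   (`set_name`, `gene`).
#' @param universe Character vector of all tested genes.
#' @return Tibble (`set_name`, `k`, `K`, `n`, `N`, `fold_enrichment`, `p`,
#'   `p_adj`), classed `"enrichment_result"`, attribute
#'   `method = "classic hypergeometric"`.
#' @export
fisher_enrichment <- function(de_genes, sets, universe) {
  universe <- unique(as.character(universe))
  if (length(universe) == 0) {
    abort("Empty universe.", class = "splicescreen_validation_error")
  }
  de_genes <- unique(as.character(de_genes))
  outside <- setdiff(de_genes, universe)
  if (length(outside) > 0) {
    abort(sprintf("DE gene(s) outside the universe: %s",
      paste(utils::head(outside, 5), collapse = ", ")),
      class = "splicescreen_validation_error")
  }
  if (is.data.frame(sets)) sets <- split(as.character(sets$gene), sets$set_name)
  stopifnot(is.list(sets), !is.null(names(sets)))
  N <- length(universe)
  n <- length(de_genes)
  rows <- purrr::imap_dfr(sets, function(genes, nm) {
    inset <- intersect(unique(genes), universe)
    K <- length(inset)
    if (K == 0) return(NULL)
    k <- length(intersect(inset, de_genes))
    fold <- if (n > 0) (k / n) / (K / N) else 0
    p <- if (n > 0) phyper(k - 1, K, N - K, n, lower.tail = FALSE) else 1
    tibble(set_name = nm, k = k, K = K, n = n, N = N,
      fold_enrichment = fold, p = p)
  })
  if (nrow(rows) < length(sets)) {
    inform(sprintf("%d set(s) with no genes in the universe dropped.",
      length(sets) - nrow(rows)))
  }
  if (nrow(rows) == 0) {
    abort("No gene set overlaps the universe.",
      class = "splicescreen_validation_error")
  }
  rows$p_adj <- p.adjust(rows$p, method = "BH")
  new_result(rows, "enrichment_result", method = "classic hypergeometric")
}

#' Overlay prognostic-marker annotations on a DE result
#'
#' @param de A `de_result`.
#' @param markers Tibble (`gene`, `prognosis`) or a named character vector;
#'   values must be `"favorable"` or `"unfavorable"`. Genes absent from the
#'   map keep `"none"`. Untestable genes keep their annotation with `NA`
#'   statistics.
#' @return The `de_result` with the `prognosis` column filled.
#' @export
annotate_prognostic <- function(de, markers) {
  stopifnot(inherits(de, "de_result"))
  if (length(markers) == 0 ||
      (is.data.frame(markers) && nrow(markers) == 0)) {
    return(de)
  }
  mk <- as_named_vector(markers, "prognosis", "gene")
  if (!all(mk %in% c("favorable", "unfavorable"))) {
    abort("Marker labels must be 'favorable' or 'unfavorable'.",
      class = "splicescreen_validation_error")
  }
  hit <- de$gene %in% names(mk)
  de$prognosis[hit] <- unname(mk[de$gene[hit]])
  de
}
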