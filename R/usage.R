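#' Group junctions into competing sets
#'
#' Junctions compete when they consume the same splice site of the same gene.
#' Under `shared_donor` (the default throughout the package, matching the
#' biology of an alternative terminal exon whose inclusion and exclusion
#' junctions share one 5' splice site) the anchor is the start coordinate;
#' `shared_acceptor` anchors on the end; `either_end` merges transitively over
#' both anchors; `whole_gene` pools all junctions of a gene (for sensitivity
#' analysis). Singleton sets are allowed (constitutive junctions). A junction
#' with no gene assignment is placed in its own singleton set with a warning.
#'
#' @param junctions A `junction_counts` tibble (only `junction_id` and `gene`
#'   are used).
#' @param mode Anchor mode, see Details.
#' @return A tibble (`junction_id`, `gene`, `chrom`, `start`, `end`,
#'   `set_id`), classed `"competing_sets"`, with attribute `mode`.
#' @export
build_competing_sets <- function(junctions,
                                 mode = c("shared_donor", "shared_acceptor",
                                          "either_end", "whole_gene")) {
  mode <- match.arg(mode)
  coords <- parse_junction_id(junctions$junction_id)
  coords$gene <- junctions$gene
  orphan <- is.na(coords$gene) | coords$gene == ""
  if (any(orphan)) {
    warn(sprintf("%d junction(s) without a gene assigned to singleton sets.",
      sum(orphan)))
  }
  key <- switch(mode,
    shared_donor = paste(coords$gene, coords$chrom, coords$start, sep = "|"),
    shared_acceptor = paste(coords$gene, coords$chrom, coords$end, sep = "|"),
    whole_gene = paste(coords$gene, coords$chrom, sep = "|"),
    either_end = either_end_key(coords)
  )
  # orphans always get a private set
  key[orphan] <- paste0("orphan|", coords$junction_id[orphan])
  coords$set_id <- paste0("set:", match(key, unique(key)))
  new_result(coords, "competing_sets", mode = mode)
}

# Union-find over junctions sharing a donor or an acceptor within a gene.
either_end_key <- function(coords) {
  n <- nrow(coords)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union_ <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[ri] <<- rj
  }
  for (anchor in list(
    paste(coords$gene, coords$chrom, coords$start, sep = "|"),
    paste(coords$gene, coords$chrom, coords$end, sep = "|")
  )) {
    for (grp in split(seq_len(n), anchor)) {
      if (length(grp) > 1) for (i in grp[-1]) union_(grp[1], i)
    }
  }
  vapply(seq_len(n), find, 0L)
}

#' Per-sample junction usage within competing sets
#'
#' For junction `j` in sample `s` with normalized reads `N_js = count * Ns`,
#' usage is `N_js / sum(N_ks, k in set(j))`: the fraction of normalized
#' split-read support the junction receives among junctions competing for the
#' same splice site. Usage is missing (`NA`, never 0) when the set's
#' normalized denominator is below `min_coverage`, which avoids 0/0 and
#' high-variance estimates at low coverage.
#'
#' @param counts A `junction_counts` tibble.
#' @param factors [compute_depth_factors()] output covering the samples.
#' @param sets [build_competing_sets()] output for the same junctions.
#' @param min_coverage Minimum normalized reads in the denominator before a
#'   usage value is declared (default 8).
#' @return A long tibble (`junction_id`, `sample_id`, `usage`,
#'   `denominator_reads`), classed `"usage_table"`; within every
#'   (sample, set) with a declared denominator the usages sum to 1.
#' @export
compute_junction_usage <- function(counts, factors, sets, min_coverage = 8) {
  scols <- intersect(sample_cols(counts), factors$sample_id)
  dropped <- setdiff(sample_cols(counts), factors$sample_id)
  if (length(scols) == 0) {
    abort("Depth factors cover none of the count samples.",
      class = "splicescreen_validation_error")
  }
  if (length(dropped) > 0) {
    inform(sprintf("%d sample(s) without depth factors skipped.", length(dropped)))
  }
  ns <- setNames(factors$norm_factor, factors$sample_id)
  long <- counts[, c("junction_id", scols)] |>
    tidyr::pivot_longer(-"junction_id", names_to = "sample_id", values_to = "count") |>
    dplyr::mutate(normalized = .data$count * unname(ns[.data$sample_id])) |>
    dplyr::left_join(sets[, c("junction_id", "set_id")], by = "junction_id") |>
    dplyr::group_by(.data$set_id, .data$sample_id) |>
    dplyr::mutate(denominator_reads = sum(.data$normalized)) |>
    dplyr::ungroup() |>
    dplyr::mutate(usage = dplyr::if_else(
      .data$denominator_reads >= min_coverage & .data$denominator_reads > 0,
      .data$normalized / .data$denominator_reads, NA_real_)) |>
    dplyr::select("junction_id", "sample_id", "usage", "denominator_reads")
  new_result(long, "usage_table",
    min_coverage = min_coverage, mode = attr(sets, "mode"))
}

#' Percent spliced in (PSI) from inclusion and exclusion reads
#'
#' `psi = 100 * inclusion / (inclusion + exclusion)` on the 0-100 percent
#' scale, missing when the total normalized read support for the event is
#' below `min_coverage` (and always missing at zero total).
#'
#' @param inclusion_reads,exclusion_reads Non-negative (normalized) read
#'   counts supporting inclusion and exclusion; vectorized.
#' @param min_coverage Minimum event total before PSI is declared; the
#'   default 0 declares PSI whenever any reads support the event.
#' @return A tibble (`inclusion_reads`, `exclusion_reads`, `total_reads`,
#'   `psi`).
#' @export
#' @examples
#' compute_psi(30, 10) # 75%
compute_psi <- function(inclusion_reads, exclusion_reads, min_coverage = 0) {
  if (any(inclusion_reads < 0, na.rm = TRUE) || any(exclusion_reads < 0, na.rm = TRUE)) {
    abort("Read counts must be non-negative.", class = "splicescreen_validation_error")
  }
  total <- inclusion_reads + exclusion_reads
  psi <- ifelse(total > 0 & total >= min_coverage,
    100 * inclusion_reads / total, NA_real_)
  tibble(inclusion_reads = inclusion_reads, exclusion_reads = exclusion_reads,
    total_reads = total, psi = psi)
}
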