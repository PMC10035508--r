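# Independent oracles used to freeze expected values. These deliberately use
# brute force / closed forms, never the package's own code paths.

# Pearson r and two-sided p from the textbook formulas.
oracle_pearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(t), df = n - 2))
}

# Exact two-sided Wilcoxon rank-sum p by enumerating all label assignments.
oracle_wilcox_exact <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  rk <- rank(pooled)
  u_obs <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(length(pooled), n1)
  u_all <- apply(combs, 2, function(idx) sum(rk[idx]) - n1 * (n1 + 1) / 2)
  p_le <- mean(u_all <= u_obs)
  p_ge <- mean(u_all >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Closed-form upper-tail hypergeometric P(X >= k).
oracle_hyper_tail <- function(k, K, n, N) {
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Random junction count tibble for property tests.
random_junction_counts <- function(n_junc = 6, n_samp = 4, gene = "G1",
                                   max_count = 500) {
  starts <- sample(1000:2000, n_junc, replace = TRUE)
  ends <- starts + sample(50:500, n_junc, replace = TRUE)
  ids <- sprintf("chr1:%d-%d", starts, ends)
  while (anyDuplicated(ids)) {
    ends <- starts + sample(50:500, n_junc, replace = TRUE)
    ids <- sprintf("chr1:%d-%d", starts, ends)
  }
  counts <- matrix(rpois(n_junc * n_samp, max_count / 4), n_junc)
  df <- dplyr::bind_cols(
    tibble::tibble(junction_id = ids, gene = gene),
    tibble::as_tibble(counts, .name_repair = ~sprintf("s%02d", seq_len(n_samp)))
  )
  validate_junction_counts(df)
}

# Two-junction shared-donor fixture with prescribed counts (one gene).
two_junction_counts <- function(counts_mat, samples = NULL) {
  samples <- samples %||% sprintf("s%d", seq_len(ncol(counts_mat)))
  df <- dplyr::bind_cols(
    tibble::tibble(
      junction_id = c("chr1:100-200", "chr1:100-300"),
      gene = "G1"
    ),
    tibble::as_tibble(counts_mat, .name_repair = ~samples)
  )
  validate_junction_counts(df)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
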