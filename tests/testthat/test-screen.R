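make_expr <- function(mat, genes, samples) {
  validate_expression(dplyr::bind_cols(
    tibble::tibble(gene = genes),
    tibble::as_tibble(mat, .name_repair = ~samples)))
}

test_that("self- and anti-correlated usage give r = 1 and r = -1", {
  u <- c(s1 = 0.1, s2 = 0.4, s3 = 0.7, s4 = 0.9)
  expr <- make_expr(rbind(u, 1 - u), c("SELF", "ANTI"), names(u))
  scr <- correlate_rbp_usage(expr, u)
  expect_equal(scr$r[scr$rbp == "SELF"], 1)
  expect_equal(scr$r[scr$rbp == "ANTI"], -1)
  expect_equal(scr$sign[scr$rbp == "SELF"], "+")
  expect_equal(scr$sign[scr$rbp == "ANTI"], "-")
  # alone, perfect self-correlation is rank 1
  solo <- correlate_rbp_usage(make_expr(rbind(u), "SELF", names(u)), u)
  expect_equal(solo$rank, 1L)
})

test_that("r and p match the closed-form Pearson/t oracle", {
  x <- 1:5
  y <- c(2, 1, 4, 3, 5)
  expr <- make_expr(matrix(x, 1), "R1", sprintf("s%d", 1:5))
  u <- setNames(y, sprintf("s%d", 1:5))
  scr <- correlate_rbp_usage(expr, u)
  orc <- oracle_pearson(x, y)
  expect_equal(scr$r, orc$r, tolerance = 1e-12)
  expect_equal(scr$p, orc$p, tolerance = 1e-12)
  expect_equal(scr$n, 5L)
})

test_that("zero-variance and short RBPs are untestable, not ranked", {
  u <- c(s1 = 0.1, s2 = 0.5, s3 = 0.9)
  expr <- make_expr(rbind(c(1, 2, 3), c(5, 5, 5)), c("OK", "FLAT"),
    names(u))
  scr <- correlate_rbp_usage(expr, u)
  expect_equal(scr$rbp, "OK")
  expect_equal(attr(scr, "untestable")$rbp, "FLAT")

  u2 <- c(s1 = 0.1, s2 = 0.5, s3 = NA)
  expr2 <- make_expr(matrix(1:3, 1), "OK", names(u2))
  expect_error(correlate_rbp_usage(expr2, u2),
    class = "splicescreen_validation_error")
})

test_that("ties in |r| break by p then symbol, deterministically", {
  u <- c(s1 = 0.1, s2 = 0.4, s3 = 0.6, s4 = 0.9)
  expr <- make_expr(rbind(u * 2, 1 - u), c("BBB", "AAA"), names(u))
  scr <- correlate_rbp_usage(expr, u)
  # both |r| = 1, p equal -> lexicographic
  expect_equal(scr$rbp, c("AAA", "BBB"))
  scr2 <- correlate_rbp_usage(expr[2:1, ], u)
  expect_equal(scr2$rbp, c("AAA", "BBB"))
})

test_that("screen is invariant to sample permutation and positive rescaling", {
  withr::local_seed(41)
  n <- 20
  samples <- sprintf("s%02d", 1:n)
  u <- setNames(runif(n), samples)
  mat <- matrix(rlnorm(5 * n), 5)
  expr <- make_expr(mat, sprintf("R%d", 1:5), samples)
  scr <- correlate_rbp_usage(expr, u)

  perm <- sample(n)
  expr_p <- make_expr(mat[, perm], sprintf("R%d", 1:5), samples[perm])
  scr_p <- correlate_rbp_usage(expr_p, u)
  expect_equal(tidy(scr_p), tidy(scr), tolerance = 1e-12)

  mat2 <- mat
  mat2[3, ] <- mat[3, ] * 1000
  scr_s <- correlate_rbp_usage(make_expr(mat2, sprintf("R%d", 1:5), samples), u)
  expect_equal(tidy(scr_s)$r, tidy(scr)$r, tolerance = 1e-12)
})

test_that("rank_candidates keeps top-k with warnings on overflow", {
  u <- c(s1 = 0.1, s2 = 0.4, s3 = 0.6, s4 = 0.9)
  mat <- rbind(u, 1 - u, u + c(0.3, -0.2, 0.1, -0.1))
  scr <- correlate_rbp_usage(make_expr(mat, c("A", "B", "C"), names(u)), u)
  expect_equal(nrow(rank_candidates(scr, 2)), 2L)
  expect_equal(tidy(rank_candidates(scr, 3)), tidy(scr))
  expect_warning(allr <- rank_candidates(scr, 10), "exceeds")
  expect_equal(nrow(allr), 3L)
  expect_error(rank_candidates(scr, 0), class = "splicescreen_validation_error")
})

test_that("concordance verdicts follow the sign rule", {
  u <- c(s1 = 0.9, s2 = 0.7, s3 = 0.3, s4 = 0.1)
  # NEG correlates negatively with usage, POS positively
  mat <- rbind(1 - u, u)
  scr <- correlate_rbp_usage(make_expr(mat, c("NEG", "POS"), names(u)), u)

  tsamp <- sprintf("t%d", 1:12)
  groups <- tibble::tibble(sample_id = tsamp,
    stratum = rep(c("high", "low"), each = 6))
  # NEG strictly lower in every high-PSI tumor -> concordant repressor
  # POS also lower in high -> discordant for a positive correlate
  tmat <- rbind(c(1:6, 101:106), c(1:6, 101:106))
  texpr <- make_expr(tmat, c("NEG", "POS"), tsamp)
  verdict <- concordance_filter(scr, texpr, groups, alpha = 0.05)
  expect_true(verdict$concordant[verdict$rbp == "NEG"])
  expect_equal(verdict$tumor_de_sign[verdict$rbp == "NEG"], "lower_in_highPSI")
  expect_false(verdict$concordant[verdict$rbp == "POS"])

  # SFRS9 pattern: negative correlation but HIGHER in high-PSI tumors
  tmat2 <- rbind(c(101:106, 1:6), c(101:106, 1:6))
  verdict2 <- concordance_filter(scr, make_expr(tmat2, c("NEG", "POS"), tsamp),
    groups, alpha = 0.05)
  expect_false(verdict2$concordant[verdict2$rbp == "NEG"])
  expect_equal(verdict2$tumor_de_sign[verdict2$rbp == "NEG"], "higher_in_highPSI")
  expect_true(verdict2$concordant[verdict2$rbp == "POS"])

  # non-significant difference -> ns, not concordant
  tmat3 <- rbind(rep(c(1, 2), 6), rep(c(2, 1), 6))
  verdict3 <- concordance_filter(scr, make_expr(tmat3, c("NEG", "POS"), tsamp),
    groups, alpha = 0.05)
  expect_true(all(verdict3$tumor_de_sign == "ns"))
  expect_false(any(verdict3$concordant))

  # a group with < 2 samples is an error
  g2 <- tibble::tibble(sample_id = tsamp,
    stratum = c("high", rep("low", 11)))
  expect_error(concordance_filter(scr, texpr, g2),
    class = "splicescreen_validation_error")
})
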