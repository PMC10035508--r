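test_that("competing sets follow the anchor mode", {
  jc <- two_junction_counts(matrix(c(1, 1), nrow = 2)) # chr1:100-200, chr1:100-300
  sd <- build_competing_sets(jc, mode = "shared_donor")
  expect_equal(length(unique(sd$set_id)), 1L)
  sa <- build_competing_sets(jc, mode = "shared_acceptor")
  expect_equal(length(unique(sa$set_id)), 2L)
  expect_equal(attr(sd, "mode"), "shared_donor")
})

test_that("random splice graphs group identically to a brute-force oracle", {
  withr::local_seed(31)
  for (rep in 1:5) {
    n <- 30
    starts <- sample(seq(100, 400, by = 20), n, replace = TRUE)
    ends <- starts + sample(seq(10, 200, by = 10), n, replace = TRUE)
    ids <- sprintf("chrX:%d-%d", starts, ends)
    keep <- !duplicated(ids)
    df <- dplyr::bind_cols(
      tibble::tibble(junction_id = ids[keep], gene = "G1"),
      tibble::as_tibble(matrix(1L, sum(keep), 1), .name_repair = ~"s1"))
    jc <- validate_junction_counts(df)
    sets <- build_competing_sets(jc, mode = "shared_donor")
    # oracle: partition by start coordinate
    oracle <- split(jc$junction_id, starts[keep])
    got <- split(sets$junction_id, sets$set_id)
    normalize <- function(p) unname(lapply(p[order(vapply(p, min, ""))], sort))
    expect_equal(normalize(got), normalize(oracle))
  }
})

test_that("junctions without a gene become warned singletons", {
  df <- dplyr::bind_cols(
    tibble::tibble(junction_id = c("chr1:1-5", "chr1:1-9"),
      gene = c(NA, NA)),
    tibble::as_tibble(matrix(1L, 2, 1), .name_repair = ~"s1"))
  # validation requires gene column present; NA genes allowed at set building
  class(df) <- c("junction_counts", class(df))
  expect_warning(sets <- build_competing_sets(df), "without a gene")
  expect_equal(length(unique(sets$set_id)), 2L)
})

test_that("usage reproduces the 85/15 split and the singleton/missing rules", {
  jc <- two_junction_counts(matrix(c(85, 15), nrow = 2))
  fac <- compute_depth_factors(jc)
  sets <- build_competing_sets(jc)
  use <- compute_junction_usage(jc, fac, sets, min_coverage = 8)
  expect_equal(use$usage[use$junction_id == "chr1:100-200"], 0.85)
  expect_equal(use$usage[use$junction_id == "chr1:100-300"], 0.15)

  # singleton set with positive reads -> usage 1
  df <- dplyr::bind_cols(
    tibble::tibble(junction_id = c("chr1:100-200", "chr1:500-600"),
      gene = "G1"),
    tibble::as_tibble(matrix(c(40L, 60L), 2, 1), .name_repair = ~"s1"))
  jc2 <- validate_junction_counts(df)
  use2 <- compute_junction_usage(jc2, compute_depth_factors(jc2),
    build_competing_sets(jc2), min_coverage = 8)
  expect_equal(use2$usage, c(1, 1))

  # zero denominator -> missing, never 0
  jc3 <- two_junction_counts(matrix(c(50L, 50L, 0L, 0L), nrow = 2))
  suppressWarnings(fac3 <- compute_depth_factors(jc3))
  use3 <- compute_junction_usage(jc3, fac3, build_competing_sets(jc3),
    min_coverage = 0)
  expect_true(all(is.na(use3$usage[use3$sample_id == "s2"])) ||
    !"s2" %in% use3$sample_id)
})

test_that("denominators below min_coverage yield missing usage", {
  jc <- two_junction_counts(matrix(c(3L, 2L, 100L, 100L), nrow = 2))
  fac <- tibble::tibble(sample_id = c("s1", "s2"), total_reads = c(5, 200),
    norm_factor = c(1, 1))
  use <- compute_junction_usage(jc, fac, build_competing_sets(jc),
    min_coverage = 8)
  expect_true(all(is.na(use$usage[use$sample_id == "s1"])))
  expect_false(anyNA(use$usage[use$sample_id == "s2"]))
})

test_that("usages sum to one within every covered competing set", {
  withr::local_seed(32)
  for (rep in 1:5) {
    jc <- random_junction_counts(n_junc = 12, n_samp = 5)
    fac <- compute_depth_factors(jc)
    sets <- build_competing_sets(jc)
    use <- compute_junction_usage(jc, fac, sets, min_coverage = 8)
    sums <- use |>
      dplyr::left_join(sets[, c("junction_id", "set_id")], by = "junction_id") |>
      dplyr::filter(!is.na(.data$usage)) |>
      dplyr::group_by(.data$set_id, .data$sample_id) |>
      dplyr::summarise(s = sum(.data$usage), .groups = "drop")
    expect_true(all(abs(sums$s - 1) < 1e-9))
  }
})

test_that("usage is invariant to uniform scaling of a sample's counts", {
  withr::local_seed(33)
  jc <- random_junction_counts(n_junc = 8, n_samp = 3)
  jc2 <- jc
  jc2$s01 <- jc$s01 * 7L
  jc2 <- validate_junction_counts(jc2)
  u1 <- compute_junction_usage(jc, compute_depth_factors(jc),
    build_competing_sets(jc), min_coverage = 0)
  u2 <- compute_junction_usage(jc2, compute_depth_factors(jc2),
    build_competing_sets(jc2), min_coverage = 0)
  expect_equal(u2$usage, u1$usage, tolerance = 1e-12)
})

test_that("either_end mode merges transitively across shared donors and acceptors", {
  # j1,j2 share a donor; j2,j3 share an acceptor -> one set of three
  df <- dplyr::bind_cols(
    tibble::tibble(
      junction_id = c("chr1:100-200", "chr1:100-300", "chr1:150-300",
        "chr1:900-950"),
      gene = "G1"),
    tibble::as_tibble(matrix(1L, 4, 1), .name_repair = ~"s1"))
  jc <- validate_junction_counts(df)
  ee <- build_competing_sets(jc, "either_end")
  sizes <- sort(unname(table(ee$set_id)))
  expect_equal(as.integer(sizes), c(1L, 3L))
})

test_that("PSI follows 100 * inc / total with the missingness rule", {
  expect_equal(compute_psi(30, 10)$psi, 75)
  expect_equal(compute_psi(0, 50)$psi, 0)
  expect_true(is.na(compute_psi(0, 0)$psi))
  expect_true(is.na(compute_psi(3, 2, min_coverage = 8)$psi))
  expect_equal(compute_psi(c(30, 0), c(10, 0))$psi, c(75, NA))
  expect_error(compute_psi(-1, 5), class = "splicescreen_validation_error")
})
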