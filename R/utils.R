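# Internal helpers shared across modules.

# Metadata (non-sample) columns recognised in wide matrices.
.meta_cols <- c("junction_id", "gene")

sample_cols <- function(x) setdiff(names(x), .meta_cols)

#' Parse junction identifiers of the form "chrom:start-end"
#'
#' Coordinates are 1-based with inclusive ends (GTEx junction-file
#' convention); `start < end` is required so that genomic identity is
#' unambiguous.
#'
#' @param ids Character vector of junction identifiers.
#' @return A tibble with columns `junction_id`, `chrom`, `start`, `end`.
#' @export
#' @examples
#' parse_junction_id("chr3:189500001-189560000")
parse_junction_id <- function(ids) {
  stopifnot(is.character(ids))
  m <- regexec("^([^:[:space:]]+):([0-9]+)-([0-9]+)$", ids)
  parts <- regmatches(ids, m)
  bad <- ids[lengths(parts) != 4L]
  if (length(bad) > 0) {
    abort(sprintf(
      "Malformed junction id(s) (expected 'chrom:start-end'): %s",
      paste(utils::head(bad, 5), collapse = ", ")
    ), class = "splicescreen_format_error")
  }
  out <- tibble(
    junction_id = ids,
    chrom = vapply(parts, `[[`, "", 2L),
    start = as.integer(vapply(parts, `[[`, "", 3L)),
    end = as.integer(vapply(parts, `[[`, "", 4L))
  )
  rev <- out$start >= out$end
  if (any(rev)) {
    abort(sprintf(
      "Junction id(s) with start >= end: %s",
      paste(utils::head(out$junction_id[rev], 5), collapse = ", ")
    ), class = "splicescreen_validation_error")
  }
  out
}

# Validate the numeric block of a wide matrix-like tibble, naming the first
# offending row/column in the error.
check_count_block <- function(df, id_col, integer = TRUE, what = "count") {
  scols <- sample_cols(df)
  if (length(scols) == 0) {
    abort("No sample columns found.", class = "splicescreen_format_error")
  }
  for (sc in scols) {
    v <- df[[sc]]
    if (!is.numeric(v)) {
      abort(sprintf("Column '%s' is not numeric.", sc),
        class = "splicescreen_validation_error")
    }
    bad <- which(is.na(v) | v < 0 | (integer & (v != floor(v))))
    if (length(bad) > 0) {
      abort(sprintf(
        "Invalid %s at row '%s', column '%s': %s",
        what, df[[id_col]][bad[1]], sc, format(v[bad[1]])
      ), class = "splicescreen_validation_error")
    }
  }
  invisible(df)
}

as_matrix_block <- function(df) {
  scols <- sample_cols(df)
  m <- as.matrix(df[, scols, drop = FALSE])
  rownames(m) <- df[[intersect(.meta_cols, names(df))[1]]]
  m
}

# Coerce a named vector or two-column data frame to a named vector; the id
# column defaults to `name_col` when present, else the first column (sample
# and patient tables differ only in that column's name).
as_named_vector <- function(x, value_col, name_col = NULL) {
  if (is.data.frame(x)) {
    if (is.null(name_col) || !name_col %in% names(x)) name_col <- names(x)[[1]]
    setNames(x[[value_col]], x[[name_col]])
  } else if (!is.null(names(x))) {
    x
  } else {
    abort(sprintf("Expected a named vector or a data frame with a '%s' column.",
      value_col))
  }
}

new_result <- function(df, class, ...) {
  attrs <- list(...)
  for (nm in names(attrs)) attr(df, nm) <- attrs[[nm]]
  class(df) <- c(class, class(df))
  df
}
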