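#' Read a splice-junction count matrix
#'
#' Reads a tab-delimited junction count table into a wide tibble with one row
#' per junction and one numeric column per sample. Junction coordinates are
#' 1-based with inclusive ends and must satisfy `start < end`.
#'
#' Two dialects are supported:
#' * `"gtex_like"`: the first two columns (whatever their headers) hold the
#'   junction identifier and the gene symbol, as in GTEx junction files.
#' * `"generic_tsv"`: columns named `junction_id` and `gene` are required.
#'
#' @param path Path to a tab-delimited text file with a header row.
#' @param dialect Input dialect, see Details.
#' @return A tibble with columns `junction_id`, `gene` and one non-negative
#'   integer column per sample, classed `"junction_counts"`.
#' @export
read_junction_counts <- function(path, dialect = c("gtex_like", "generic_tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "splicescreen_io_error")
  }
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (ncol(df) < 3) {
    abort("Junction count file needs a header with at least 3 columns (id, gene, >=1 sample).",
      class = "splicescreen_format_error")
  }
  if (dialect == "gtex_like") {
    names(df)[1:2] <- c("junction_id", "gene")
  } else if (!all(c("junction_id", "gene") %in% names(df))) {
    abort("generic_tsv dialect requires columns 'junction_id' and 'gene'.",
      class = "splicescreen_format_error")
  }
  df <- dplyr::relocate(df, "junction_id", "gene")
  validate_junction_counts(df)
}

#' Validate a junction count tibble
#'
#' Checks identifier syntax and coordinate order, uniqueness of junction ids,
#' and that every sample column holds non-negative integers.
#'
#' @param df A tibble with columns `junction_id`, `gene` and sample columns.
#' @return `df`, classed `"junction_counts"`, invisibly validated.
#' @export
validate_junction_counts <- function(df) {
  stopifnot(is.data.frame(df), all(c("junction_id", "gene") %in% names(df)))
  df <- as_tibble(df)
  if (anyDuplicated(df$junction_id)) {
    abort("Duplicated junction_id values.", class = "splicescreen_validation_error")
  }
  parse_junction_id(df$junction_id)
  check_count_block(df, "junction_id", integer = TRUE, what = "count")
  if (!inherits(df, "junction_counts")) class(df) <- c("junction_counts", class(df))
  df
}

#' Read a gene-expression matrix
#'
#' @param path Tab-delimited file; first column `gene`, remaining columns one
#'   per sample.
#' @param normalized Whether the values are already depth-normalized; recorded
#'   as an attribute. The reader is otherwise unit-agnostic (counts, RSEM,
#'   etc.), and the declared unit travels with the object.
#' @param unit Free-text unit label recorded on the object.
#' @return A tibble with column `gene` plus sample columns, classed
#'   `"expression_matrix"`, with attributes `normalized` and `unit`.
#' @export
read_expression <- function(path, normalized = FALSE, unit = "counts") {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "splicescreen_io_error")
  }
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!"gene" %in% names(df)) names(df)[1] <- "gene"
  validate_expression(df, normalized = normalized, unit = unit)
}

#' Validate an expression tibble
#' @inheritParams read_expression
#' @param df Tibble with column `gene` plus numeric sample columns.
#' @return Validated tibble classed `"expression_matrix"`.
#' @export
validate_expression <- function(df, normalized = FALSE, unit = "counts") {
  stopifnot(is.data.frame(df), "gene" %in% names(df))
  df <- as_tibble(df)
  if (anyDuplicated(df$gene)) {
    abort("Duplicated gene symbols.", class = "splicescreen_validation_error")
  }
  check_count_block(df, "gene", integer = FALSE, what = "expression value")
  attr(df, "normalized") <- isTRUE(normalized)
  attr(df, "unit") <- unit
  if (!inherits(df, "expression_matrix")) class(df) <- c("expression_matrix", class(df))
  df
}

#' Read a clinical outcome table
#'
#' Requires columns `patient_id`, `time_days` and `event` (1 = death observed,
#' 0 = censored). Rows with missing or non-positive follow-up time are dropped
#' with a warning stating the count; any `event` value outside \{0, 1\} is an
#' error.
#'
#' @param path Tab-delimited file.
#' @return Tibble with the validated columns (extra columns kept as
#'   covariates); attribute `n_dropped` records removed rows.
#' @export
read_clinical_table <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "splicescreen_io_error")
  }
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_clinical(df)
}

#' Validate a clinical table
#' @param df Data frame with `patient_id`, `time_days`, `event`.
#' @return Validated tibble; rows with non-positive time dropped (warning).
#' @export
validate_clinical <- function(df) {
  need <- c("patient_id", "time_days", "event")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    abort(sprintf("Clinical table missing column(s): %s", paste(miss, collapse = ", ")),
      class = "splicescreen_format_error")
  }
  df <- as_tibble(df)
  bad_event <- !df$event %in% c(0, 1)
  if (any(bad_event)) {
    abort(sprintf(
      "event must be 0 or 1; offending patient(s): %s",
      paste(utils::head(df$patient_id[bad_event], 5), collapse = ", ")
    ), class = "splicescreen_validation_error")
  }
  keep <- !is.na(df$time_days) & df$time_days > 0
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    warn(sprintf("Dropped %d row(s) with missing or non-positive time_days.", n_dropped))
  }
  out <- df[keep, , drop = FALSE]
  out$event <- as.integer(out$event)
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Read a sample-attribute table
#'
#' @param path Tab-delimited file with columns `sample_id` and `tissue`
#'   (required) and optionally `condition` (one of `normal`, `tumor`, `NA`).
#' @return Validated tibble with columns `sample_id`, `tissue`, `condition`.
#' @export
read_sample_attributes <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("sample_id", "tissue")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    abort(sprintf("Attribute table missing column(s): %s", paste(miss, collapse = ", ")),
      class = "splicescreen_format_error")
  }
  if (any(is.na(df$tissue) | df$tissue == "")) {
    abort("tissue labels must be non-empty.", class = "splicescreen_validation_error")
  }
  if (!"condition" %in% names(df)) df$condition <- NA_character_
  badc <- !is.na(df$condition) & !df$condition %in% c("normal", "tumor")
  if (any(badc)) {
    abort("condition must be 'normal', 'tumor' or NA.",
      class = "splicescreen_validation_error")
  }
  as_tibble(df[, c("sample_id", "tissue", "condition",
    setdiff(names(df), c("sample_id", "tissue", "condition")))])
}

#' Read gene sets (two-column TSV or GMT)
#'
#' @param path File path.
#' @param format `"tsv"` expects columns `set_name`, `gene`; `"gmt"` is the
#'   usual one-set-per-line dialect (name, description, genes...).
#' @return A named list of character vectors (one per set), with a
#'   `descriptions` attribute. Empty sets are an error.
#' @export
read_gene_sets <- function(path, format = c("tsv", "gmt")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "splicescreen_io_error")
  }
  if (format == "tsv") {
    df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    if (!all(c("set_name", "gene") %in% names(df))) {
      abort("Gene-set TSV requires columns 'set_name' and 'gene'.",
        class = "splicescreen_format_error")
    }
    sets <- split(as.character(df$gene), df$set_name)
    desc <- setNames(rep(NA_character_, length(sets)), names(sets))
  } else {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    short <- vapply(fields, length, 0L) < 3L
    if (any(short)) {
      abort("GMT lines need at least 3 tab-separated fields.",
        class = "splicescreen_format_error")
    }
    sets <- lapply(fields, function(f) unique(f[-(1:2)]))
    names(sets) <- vapply(fields, `[[`, "", 1L)
    desc <- setNames(vapply(fields, `[[`, "", 2L), names(sets))
  }
  if (any(lengths(sets) == 0)) {
    abort("Gene sets must be non-empty.", class = "splicescreen_validation_error")
  }
  attr(sets, "descriptions") <- desc
  sets
}

#' Read an EMSA titration table
#'
#' @param path Tab-delimited file with columns `probe`, `replicate`,
#'   `conc_nM` (protein concentration, nmol/L) and `bound_frac`.
#' @return Tibble with columns `probe`, `replicate`, `conc`, `bound_frac`.
#' @export
read_titration <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("probe", "replicate", "conc_nM", "bound_frac")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    abort(sprintf("Titration table missing column(s): %s", paste(miss, collapse = ", ")),
      class = "splicescreen_format_error")
  }
  if (any(df$conc_nM < 0)) {
    abort("Concentrations must be >= 0.", class = "splicescreen_validation_error")
  }
  tibble(probe = as.character(df$probe), replicate = df$replicate,
    conc = as.numeric(df$conc_nM), bound_frac = as.numeric(df$bound_frac))
}

#' Write a table with a byte-stable layout
#'
#' TSV output uses a fixed column order (as given), tab separator, `.` decimal
#' mark and the literal string `NA` for missing values, independent of locale.
#' JSON output serialises rows as objects with `null` for missing values.
#'
#' @param x A data frame.
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  stopifnot(is.data.frame(x))
  if (format == "tsv") {
    readr::write_tsv(as_tibble(as.data.frame(x)), path, na = "NA", progress = FALSE)
  } else {
    jsonlite::write_json(as.data.frame(x), path,
      dataframe = "rows", na = "null", digits = NA, auto_unbox = TRUE)
  }
  invisible(path)
}
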