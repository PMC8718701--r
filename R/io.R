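# CSV interchange (tab auto-detected). Genotypes travel as small
# integers; relationship matrices and design blocks as floating point.

detect_delim <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) abort(sprintf("'%s' is empty.", path))
  if (grepl("\t", first) && !grepl(",", first)) "\t" else ","
}

#' Read a marker matrix from CSV/TSV
#'
#' Expects a header row of marker ids with the line id in the first
#' column; the body must be 0/1/2 allele counts with no missing cells
#' (imputation belongs upstream). Duplicate line ids and out-of-coding
#' values are rejected with the offending coordinates.
#'
#' @param path File path.
#' @return Marker tibble: `line_id` (character) plus integer marker
#'   columns.
#' @export
read_markers <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: '%s'", path))
  df <- readr::read_delim(path, delim = detect_delim(path),
                          show_col_types = FALSE, progress = FALSE)
  if (nrow(df) == 0L) abort(sprintf("'%s' has a header but no data rows.", path))
  names(df)[1L] <- "line_id"
  df$line_id <- as.character(df$line_id)
  validate_markers(df) # errors name line/marker coordinates
  dplyr::mutate(tibble::as_tibble(df),
                dplyr::across(-"line_id", as.integer))
}

#' Read a long-format phenotype table from CSV/TSV
#'
#' Requires columns `line_id`, `env_id`, `value`. One record per
#' (line, environment) pair; unbalanced tables (missing cells) are
#' accepted.
#'
#' @param path File path.
#' @return Phenotype tibble `(line_id, env_id, value)` with lines and
#'   environments in first-appearance order.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: '%s'", path))
  df <- readr::read_delim(path, delim = detect_delim(path),
                          show_col_types = FALSE, progress = FALSE)
  missing_cols <- setdiff(c("line_id", "env_id", "value"), names(df))
  if (length(missing_cols)) {
    abort(sprintf("phenotype file lacks column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  validate_phenotypes(df[, c("line_id", "env_id", "value")])
}

#' Validate (and normalise) a phenotype table
#'
#' @param pheno Data frame with columns `line_id`, `env_id`, `value`.
#' @return Tibble with character ids and finite numeric values; errors
#'   on duplicated (line, environment) records.
#' @export
validate_phenotypes <- function(pheno) {
  if (!is.data.frame(pheno) ||
      !all(c("line_id", "env_id", "value") %in% names(pheno))) {
    abort("`pheno` must have columns line_id, env_id, value.")
  }
  out <- tibble::tibble(line_id = as.character(pheno$line_id),
                        env_id = as.character(pheno$env_id),
                        value = as.numeric(pheno$value))
  if (!all(is.finite(out$value))) abort("phenotype values must be finite.")
  dup <- duplicated(out[, c("line_id", "env_id")])
  if (any(dup)) {
    abort(sprintf("duplicated (line, environment) record(s), e.g. (%s, %s).",
                  out$line_id[which(dup)[1L]], out$env_id[which(dup)[1L]]))
  }
  out
}

#' Write markers / phenotypes / a relationship matrix to CSV
#'
#' Round-trips with [read_markers()] and [read_phenotypes()]; the
#' relationship matrix is written with line ids as both header and
#' first column.
#'
#' @param x The object (marker tibble, phenotype tibble, or
#'   `genomic_relationship`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_markers <- function(x, path) {
  readr::write_csv(x, path)
  invisible(path)
}

#' @rdname write_markers
#' @export
write_phenotypes <- function(x, path) {
  readr::write_csv(validate_phenotypes(x), path)
  invisible(path)
}

#' @rdname write_markers
#' @export
write_relationship <- function(x, path) {
  G <- if (inherits(x, "genomic_relationship")) x$G else as.matrix(x)
  readr::write_csv(tibble::as_tibble(G, rownames = "line_id"), path)
  invisible(path)
}
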