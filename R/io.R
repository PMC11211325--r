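# Tabular I/O. TSV is the default dialect (region labels may contain
# spaces); comma is accepted via `delimiter`. A header row is mandatory
# everywhere, and loading never reorders or drops rows.

#' Load a region-by-time series matrix
#'
#' Reads a delimited text file whose first column carries region labels and
#' remaining columns the time points. Rows with any non-numeric cell are
#' rejected with an error naming the offending region; duplicate labels and
#' ragged rows are also hard errors.
#'
#' @param path file path.
#' @param delimiter field separator, `"\t"` (default) or `","`.
#' @param subjectId optional subject identifier stored as an attribute.
#' @return Numeric matrix (regions x timepoints) with rownames = labels and
#'   attribute `subjectId`.
#' @export
loadTimeSeries <- function(path, delimiter = "\t", subjectId = NULL) {
  if (!file.exists(path))
    fcStop("missing_file", "file not found: %s", path)
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = delimiter,
                      colClasses = "character", check.names = FALSE,
                      quote = "\"", comment.char = ""),
    error = function(e) fcStop("ragged_rows",
                               "cannot parse '%s': %s", path,
                               conditionMessage(e)))
  if (ncol(df) < 4L)
    fcStop("bad_shape", "need a label column plus >= 3 timepoints in %s",
           path)
  labs <- df[[1]]
  if (anyDuplicated(labs))
    fcStop("duplicate_region", "duplicate region label(s): %s",
           paste(unique(labs[duplicated(labs)]), collapse = ", "))
  vals <- suppressWarnings(
    vapply(df[-1], as.numeric, numeric(nrow(df))))
  vals <- matrix(vals, nrow = nrow(df))
  bad <- which(apply(vals, 1L, anyNA))
  if (length(bad))
    fcStop("non_numeric", "non-numeric cell(s) in row(s): %s",
           paste(labs[bad], collapse = ", "))
  rownames(vals) <- labs
  if (nrow(vals) < 2L)
    fcStop("bad_shape", "need at least 2 regions")
  attr(vals, "subjectId") <- subjectId
  fcLog("io", sprintf("loaded time series %s: %d x %d", basename(path),
                      nrow(vals), ncol(vals)))
  vals
}

#' Write a time series matrix
#'
#' @param ts regions x timepoints matrix with rownames.
#' @param path output path.
#' @param delimiter field separator.
#' @export
writeTimeSeries <- function(ts, path, delimiter = "\t") {
  df <- data.frame(region = rownames(ts), ts, check.names = FALSE)
  colnames(df) <- c("region", paste0("t", seq_len(ncol(ts))))
  utils::write.table(df, path, sep = delimiter, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Load a region-to-network parcellation table
#'
#' Expects columns `region`, optional `hemisphere`, and `network`. Network
#' names must come from the seven-name vocabulary ([networkNames()]) when
#' `strict = TRUE`.
#'
#' @param path file path.
#' @param delimiter field separator.
#' @param strict error on unknown network names (default); when `FALSE`,
#'   rows with unknown networks are dropped with a warning.
#' @return A [NetworkParcellation-class].
#' @export
loadParcellation <- function(path, delimiter = "\t", strict = TRUE) {
  if (!file.exists(path))
    fcStop("missing_file", "file not found: %s", path)
  df <- utils::read.table(path, header = TRUE, sep = delimiter,
                          colClasses = "character", check.names = FALSE)
  need <- c("region", "network")
  if (!all(need %in% colnames(df)))
    fcStop("bad_shape", "parcellation needs columns: %s",
           paste(need, collapse = ", "))
  if (!strict) {
    dropped <- sum(!df$network %in% networkNames())
    if (dropped) warning(sprintf("dropping %d rows with unknown networks",
                                 dropped))
  }
  hemi <- if ("hemisphere" %in% colnames(df)) df$hemisphere else NULL
  NetworkParcellation(df$region, df$network, hemisphere = hemi,
                      strict = strict)
}

#' Write a results table with deterministic formatting
#'
#' Serializes a data.frame (or a homogeneous list of records) with a fixed
#' column order and numeric columns rounded to `digits` significant digits.
#' An empty data.frame yields a header-only file.
#'
#' @param rows data.frame, or list of named lists with identical key sets.
#' @param path output path.
#' @param delimiter field separator.
#' @param digits significant digits for numeric columns.
#' @export
writeResultsTable <- function(rows, path, delimiter = "\t", digits = 6) {
  if (is.list(rows) && !is.data.frame(rows)) {
    if (!length(rows)) fcStop("schema", "empty record list without schema")
    keys <- lapply(rows, names)
    if (!all(vapply(keys, identical, logical(1), keys[[1]])))
      fcStop("schema", "records have heterogeneous keys")
    rows <- do.call(rbind, lapply(rows, function(r)
      as.data.frame(r, stringsAsFactors = FALSE)))
  }
  if (!is.data.frame(rows)) fcStop("bad_argument", "'rows' must be tabular")
  out <- rows
  for (j in seq_along(out))
    if (is.numeric(out[[j]])) out[[j]] <- signif(out[[j]], digits)
  ok <- tryCatch({
    utils::write.table(out, path, sep = delimiter, row.names = FALSE,
                       quote = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) fcStop("unwritable", "cannot write to %s", path)
  invisible(path)
}

#' Load a square connectivity matrix
#'
#' Reads a matrix written by [writeConnectivityMatrix()]: a header-less label
#' column plus one column per region.
#'
#' @param path file path.
#' @param delimiter field separator.
#' @return Symmetric numeric matrix with region dimnames.
#' @export
loadConnectivityMatrix <- function(path, delimiter = "\t") {
  if (!file.exists(path))
    fcStop("missing_file", "file not found: %s", path)
  df <- utils::read.table(path, header = TRUE, sep = delimiter,
                          check.names = FALSE)
  m <- as.matrix(df[-1])
  rownames(m) <- df[[1]]
  assertSquareSymmetric(m, tol = 1e-8, name = basename(path))
  m
}

#' @rdname loadConnectivityMatrix
#' @param m symmetric matrix with dimnames.
#' @export
writeConnectivityMatrix <- function(m, path, delimiter = "\t") {
  df <- data.frame(region = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = delimiter, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Load a subject metadata table
#'
#' Missing values are allowed only in score columns (education, mmse, ravlt_*)
#' and propagate as NA (excluded pairwise in correlation analyses).
#'
#' @param path file path.
#' @param delimiter field separator.
#' @return data.frame with subject_id, group, age, sex and score columns.
#' @export
loadMetadata <- function(path, delimiter = "\t") {
  if (!file.exists(path))
    fcStop("missing_file", "file not found: %s", path)
  df <- utils::read.table(path, header = TRUE, sep = delimiter,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!"subject_id" %in% colnames(df))
    fcStop("bad_shape", "metadata needs a subject_id column")
  if (anyDuplicated(df$subject_id))
    fcStop("duplicate_subject", "duplicate subject ids")
  core <- intersect(c("subject_id", "group", "age", "sex"), colnames(df))
  if (anyNA(df[core]))
    fcStop("non_numeric", "missing values allowed only in score columns")
  df
}
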