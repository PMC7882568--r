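#' Survey table construction and validation
#'
#' A survey table is a data frame with one row per respondent:
#' `respondent_id` (character, auto-generated when absent), `year`
#' (survey year), `gender` (`"male"`/`"female"`), `age` (years, 18-70),
#' `education` (ordered level 1-3), `partnered` (1 = married / living
#' with spouse, 0 = single, divorced or widowed), `pgsi_raw` (integer
#' 0-27), and per catalog type one frequency column (ordinal category
#' 0 = never ... 5 = daily) and one spending column (currency >= 0).
#' Missing cells are `NA`; the missing-to-zero imputation of the
#' published analysis happens later, in feature construction, and only
#' among last-year gamblers.
#'
#' @param data data frame holding all catalog columns plus demographics.
#' @param catalog a [gcmm_catalog()].
#' @return The validated table with class `"gcmm_survey"` and the catalog
#'   attached as attribute `"catalog"`.
#' @export
as_survey <- function(data, catalog = default_catalog()) {
  check_catalog(catalog)
  need <- c("year", "gender", "age", "education", "partnered", "pgsi_raw",
            catalog$freq_column, catalog$spend_column)
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols))
    stop("survey table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (is.null(data$respondent_id))
    data$respondent_id <- sprintf("r%06d", seq_len(nrow(data)))
  data$respondent_id <- as.character(data$respondent_id)

  bad_cell <- function(col, ok) {
    v <- data[[col]]
    bad <- which(!is.na(v) & !ok(v))
    if (length(bad))
      stop(sprintf("column '%s': invalid value at row %d (value %s)",
                   col, bad[1], format(v[bad[1]])), call. = FALSE)
  }
  for (col in catalog$freq_column)
    bad_cell(col, function(v) v %in% 0:5)
  for (col in catalog$spend_column)
    bad_cell(col, function(v) is.numeric(v) & v >= 0)
  bad_cell("pgsi_raw", function(v) v %in% 0:27)
  bad_cell("gender", function(v) v %in% c("male", "female"))
  bad_cell("education", function(v) v %in% 1:3)
  bad_cell("partnered", function(v) v %in% 0:1)

  class(data) <- c("gcmm_survey", "data.frame")
  attr(data, "catalog") <- catalog
  data
}

#' Read / write a survey CSV
#'
#' The CSV must carry a header naming every catalog column; empty cells
#' are read as missing. Out-of-range frequency categories, negative
#' spending and out-of-range PGSI scores are rejected with the offending
#' column and row named.
#'
#' @param path CSV file path (UTF-8, comma separated).
#' @param catalog a [gcmm_catalog()].
#' @return `read_survey()`: a `"gcmm_survey"`; `write_survey()`: `path`,
#'   invisibly.
#' @export
read_survey <- function(path, catalog = default_catalog()) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("", "NA"))
  as_survey(raw, catalog)
}

#' @rdname read_survey
#' @param table a `"gcmm_survey"`.
#' @export
write_survey <- function(table, path) {
  stopifnot(inherits(table, "gcmm_survey"))
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Restrict to last-year gamblers
#'
#' Keeps respondents who participated in at least one game type during
#' the last year, i.e. have any non-missing frequency category >= 1.
#' All published analyses run on this subsample. Idempotent.
#'
#' @param table a `"gcmm_survey"`.
#' @return The filtered table, with attribute `"retained_fraction"`.
#' @export
filter_last_year_gamblers <- function(table) {
  stopifnot(inherits(table, "gcmm_survey"))
  catalog <- attr(table, "catalog")
  fm <- as.matrix(as.data.frame(table)[, catalog$freq_column, drop = FALSE])
  keep <- rowSums(!is.na(fm) & fm >= 1) > 0
  out <- table[keep, , drop = FALSE]
  class(out) <- class(table)
  attr(out, "catalog") <- catalog
  attr(out, "retained_fraction") <- if (nrow(table)) mean(keep) else NA_real_
  out
}

#' @export
print.gcmm_survey <- function(x, ...) {
  catalog <- attr(x, "catalog")
  cat("Survey table:", nrow(x), "respondents,",
      nrow(catalog), "game types, years:",
      paste(sort(unique(x$year)), collapse = ", "), "\n")
  invisible(x)
}
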