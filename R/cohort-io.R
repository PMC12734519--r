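# Cohort CSV schema: one header row naming every cohort column; enum values
# serialized lower-case; numeric fields written with 17 significant digits so
# that write -> read is the identity at full double precision.

#' Write a cohort to CSV
#'
#' @param cohort a validated cohort tibble.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  validate_cohort(cohort, context = "cohort to write")
  out <- as.data.frame(cohort)[, COHORT_COLUMNS, drop = FALSE]
  for (col in c("group", "sex", "longterm_control", "exam_regularity")) {
    out[[col]] <- tolower(out[[col]])
  }
  for (col in COHORT_NUMERIC_COLUMNS) {
    out[[col]] <- sprintf("%.17g", out[[col]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a cohort from CSV
#'
#' Parses and validates a cohort file: the header must name every cohort
#' column, numeric fields must parse, enum fields are matched
#' case-insensitively, and every record must satisfy the cohort invariants.
#' Errors report the offending row and field.
#'
#' @param path path to a cohort CSV (as written by [write_cohort()]).
#' @return a validated cohort tibble.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) abort_input("cohort file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, fileEncoding = "UTF-8")
  missing_cols <- setdiff(COHORT_COLUMNS, names(raw))
  if (length(missing_cols) > 0L) {
    abort_input(path, ": missing column(s): ",
                paste(missing_cols, collapse = ", "))
  }
  out <- raw[, COHORT_COLUMNS, drop = FALSE]
  for (col in COHORT_NUMERIC_COLUMNS) {
    parsed <- suppressWarnings(as.numeric(out[[col]]))
    bad <- which(is.na(parsed))
    if (length(bad) > 0L) {
      abort_input(path, ": row ", bad[1L], ", field `", col,
                  "`: unparseable number '", out[[col]][bad[1L]], "'")
    }
    out[[col]] <- parsed
  }
  for (col in c("group", "sex", "longterm_control", "exam_regularity")) {
    out[[col]] <- tolower(trimws(out[[col]]))
  }
  out$group <- toupper(out$group)
  cohort <- tibble::as_tibble(out)
  validate_cohort(cohort, context = path)
  cohort
}
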