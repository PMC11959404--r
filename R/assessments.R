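## Assessment-table validation and CSV interchange.

#' Validate an assessment table
#'
#' Checks the structural invariants of a rating table: required columns, at
#' most one row per (trainee, procedure), complexity labels from the 3-level
#' set, and — when scores are ordinal (all integer-valued) — legal scale
#' levels (autonomy 1-4, performance 1-5).  Continuous latent scores from the
#' generator are accepted without range restriction.
#'
#' @param table A data.frame with the assessment columns.
#' @param ordinal `NA` (default) to auto-detect ordinal mode from the data,
#'   or `TRUE`/`FALSE` to force the scale-range check on/off.
#' @return The table, invisibly, or an error describing the first violation.
#' @export
validate_assessments <- function(table, ordinal = NA) {
  missing_cols <- setdiff(ASSESSMENT_HEADER, names(table))
  if (length(missing_cols))
    stop("assessment table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (nrow(table) == 0L)
    stop("assessment table is empty", call. = FALSE)
  key <- paste(table$trainee_id, table$procedure_id, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (trainee_id, procedure_id) rows found", call. = FALSE)
  bad_cx <- !table$complexity %in% COMPLEXITY_LEVELS
  if (any(bad_cx))
    stop(sprintf("illegal complexity label '%s' (row %d)",
                 table$complexity[which(bad_cx)[1]], which(bad_cx)[1]),
         call. = FALSE)
  sc <- as.matrix(table[SCORE_VARS])
  if (!is.numeric(sc)) stop("scores must be numeric", call. = FALSE)
  if (is.na(ordinal)) {
    cmpl <- sc[!is.na(sc)]
    ordinal <- length(cmpl) > 0 && all(cmpl == round(cmpl))
  }
  if (ordinal) {
    for (v in SCORE_VARS) {
      x <- table[[v]]
      bad <- !is.na(x) & (x < 1 | x > SCORE_LEVELS[[v]] | x != round(x))
      if (any(bad))
        stop(sprintf("illegal %s value %s (row %d): legal levels are 1..%d",
                     v, format(x[which(bad)[1]]), which(bad)[1],
                     SCORE_LEVELS[[v]]), call. = FALSE)
    }
  }
  invisible(table)
}

#' Load an assessment table from CSV
#'
#' Reads a CSV with the documented header
#' `trainee_id,procedure_id,pgy,complexity,score_fa,score_ta,score_fp,score_tp`,
#' validates it, and applies the pairing rule: rows in which any of the four
#' scores is missing are dropped (both raters must have completed the
#' assessment), with the dropped count reported via `message()`.
#'
#' @param path Path to the CSV file.
#' @return Validated assessment `data.frame` with complete score vectors.
#' @export
load_assessments <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tab <- tryCatch(
    data.table::fread(path, data.table = FALSE, colClasses = list(
      character = c("trainee_id", "procedure_id", "complexity"))),
    error = function(e) stop("malformed CSV '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (nrow(tab) == 0L)
    stop("empty input: '", path, "' has a header but no rows", call. = FALSE)
  if (!identical(names(tab), ASSESSMENT_HEADER))
    stop("malformed header in '", path, "': expected ",
         paste(ASSESSMENT_HEADER, collapse = ","), call. = FALSE)
  incomplete <- !stats::complete.cases(tab[SCORE_VARS])
  if (any(incomplete)) {
    message(sum(incomplete),
            " row(s) dropped: incomplete score vector (pairing rule)")
    tab <- tab[!incomplete, , drop = FALSE]
    rownames(tab) <- NULL
  }
  if (nrow(tab) == 0L)
    stop("empty input: all rows of '", path,
         "' failed the pairing rule", call. = FALSE)
  validate_assessments(tab)
  tab
}

#' Write an assessment table to CSV
#'
#' Full-precision CSV writer; [load_assessments()] on the result reproduces
#' the table exactly (round trip).
#'
#' @param table Assessment data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_assessments <- function(table, path) {
  validate_assessments(table)
  data.table::fwrite(table[ASSESSMENT_HEADER], path)
  invisible(path)
}
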