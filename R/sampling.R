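## Dataset-construction rules: stratification by PGY and case complexity,
## per-procedure sample-size threshold, balanced thinning to a fixed number
## of procedures per trainee.

#' Sampling configuration for dataset construction
#'
#' @param procedures_per_trainee Number of procedures retained per trainee in
#'   the balanced design (conventionally 3).
#' @param min_trainees_per_procedure Minimum number of distinct trainees a
#'   procedure must have been assessed for to be retained (conventionally 50,
#'   chosen for stable variance-component estimation).
#' @param complexity_stratum Target complexity level (`"easiest"`,
#'   `"average"`, `"hardest"`) or `"all"`.
#' @param seed Integer seed for the thinning draw.
#' @return An object of class `sampling_config`.
#' @export
sampling_config <- function(procedures_per_trainee = 3L,
                            min_trainees_per_procedure = 50L,
                            complexity_stratum = "all",
                            seed = 1L) {
  procedures_per_trainee <- as.integer(procedures_per_trainee)
  min_trainees_per_procedure <- as.integer(min_trainees_per_procedure)
  stopifnot(procedures_per_trainee >= 1L, min_trainees_per_procedure >= 1L)
  complexity_stratum <- match.arg(complexity_stratum,
                                  c("all", COMPLEXITY_LEVELS))
  structure(list(procedures_per_trainee = procedures_per_trainee,
                 min_trainees_per_procedure = min_trainees_per_procedure,
                 complexity_stratum = complexity_stratum,
                 seed = as.integer(seed)),
            class = "sampling_config")
}

#' Partition an assessment table by (PGY, complexity) stratum
#'
#' @param table Assessment data.frame with `pgy` and `complexity` columns.
#' @return Named list of single-stratum tables; names are `"PGY<k>:<level>"`.
#'   The union of the strata equals the input; empty strata never appear
#'   (only observed label combinations are returned).
#' @export
stratify <- function(table) {
  validate_assessments(table)
  key <- paste0("PGY", table$pgy, ":", table$complexity)
  idx <- split(seq_len(nrow(table)), key)
  lapply(idx, function(i) {
    out <- table[i, , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Thin a single stratum to a balanced design
#'
#' Applies the dataset-construction rules, once each, in order:
#' 1. drop procedures assessed for fewer than
#'    `min_trainees_per_procedure` distinct trainees;
#' 2. drop trainees left with fewer than `procedures_per_trainee` procedures;
#' 3. for each surviving trainee keep exactly `procedures_per_trainee`
#'    procedures, sampled uniformly without replacement under `config$seed`.
#'
#' The output is a subset of the input rows in which every trainee appears
#' exactly `procedures_per_trainee` times.
#'
#' @param table Single-stratum assessment data.frame.
#' @param config A [sampling_config()].
#' @return Thinned assessment data.frame.  If a filter empties the design,
#'   an error of class `design_infeasible` names the responsible filter.
#' @export
sample_balanced <- function(table, config) {
  stopifnot(inherits(config, "sampling_config"))
  validate_assessments(table)
  if (length(unique(table$pgy)) > 1L ||
      length(unique(table$complexity)) > 1L)
    stop("sample_balanced expects a single (pgy, complexity) stratum; ",
         "use stratify() first", call. = FALSE)
  k <- config$procedures_per_trainee

  ## (1) per-procedure sample-size threshold
  n_by_proc <- tapply(table$trainee_id, table$procedure_id,
                      function(x) length(unique(x)))
  keep_proc <- names(n_by_proc)[n_by_proc >= config$min_trainees_per_procedure]
  tab <- table[table$procedure_id %in% keep_proc, , drop = FALSE]
  if (nrow(tab) == 0L)
    stop(design_infeasible(
      "no procedure reaches the min_trainees_per_procedure threshold"))

  ## (2) trainees with too few remaining procedures
  n_by_trainee <- tapply(tab$procedure_id, tab$trainee_id, length)
  keep_trainee <- names(n_by_trainee)[n_by_trainee >= k]
  tab <- tab[tab$trainee_id %in% keep_trainee, , drop = FALSE]
  if (nrow(tab) == 0L)
    stop(design_infeasible(
      "no trainee has procedures_per_trainee eligible procedures"))

  ## (3) uniform thinning to exactly k procedures per trainee
  set.seed(config$seed)
  rows <- split(seq_len(nrow(tab)), tab$trainee_id)
  pick <- unlist(lapply(rows, function(i) {
    if (length(i) == k) i else i[sample.int(length(i), k)]
  }), use.names = FALSE)
  out <- tab[sort(pick), , drop = FALSE]
  rownames(out) <- NULL
  out
}

design_infeasible <- function(msg) {
  structure(class = c("design_infeasible", "error", "condition"),
            list(message = paste0("design infeasible: ", msg), call = NULL))
}
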