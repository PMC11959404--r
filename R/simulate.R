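## Synthetic rating-data generator: trainees x procedures random-effects model
## with a 4-vector of scores per cell and known ground-truth components.

#' Simulation configuration for the synthetic rating generator
#'
#' Describes a complete generating model for paired operative ratings: random
#' trainee, procedure, and trainee-by-procedure effect vectors with known 4x4
#' covariance matrices, grand means on the rating scales, optional latent
#' thresholds for ordinal output, the linkage design, and a seed.
#'
#' @param n_trainees Number of trainees (>= 1).
#' @param n_procedures Number of distinct procedures (>= 1).
#' @param procedures_per_trainee Procedures linked to each trainee, sampled
#'   uniformly without replacement; `0` means fully crossed (every trainee
#'   rated on every procedure).
#' @param sigma_t,sigma_p,sigma_tp 4x4 symmetric positive-semidefinite
#'   matrices: ground-truth covariance components of the trainee, procedure,
#'   and trainee-by-procedure (interaction + residual, confounded with one
#'   observation per cell) effects, in the order of [score_variables()].
#'   Scalars are promoted to `x * diag(4)`.
#' @param grand_means Length-4 vector of grand means on the rating scales.
#' @param cutpoints `NULL` for continuous (latent) output, or a list of four
#'   strictly increasing threshold vectors with `levels - 1` entries
#'   (levels 4, 4, 5, 5): latent value in `(c[k-1], c[k]]` maps to level `k`,
#'   with `c[0] = -Inf` and `c[levels] = Inf`.
#' @param pgy Postgraduate-year label attached to every row (integer 1-5).
#' @param complexity Case-complexity label: `"easiest"`, `"average"`, or
#'   `"hardest"`.
#' @param missing_rate Probability in `[0, 1)` that a realized cell is
#'   dropped, independently per cell.
#' @param seed Integer RNG seed; identical configs give byte-identical data.
#'
#' @return An object of class `simulation_config`.
#' @seealso [generate_dataset()], [senior_truth()]
#' @export
simulation_config <- function(n_trainees,
                              n_procedures,
                              procedures_per_trainee = 0L,
                              sigma_t = diag(0.05, 4),
                              sigma_p = diag(0.02, 4),
                              sigma_tp = diag(0.25, 4),
                              grand_means = c(3.0, 2.8, 3.5, 3.3),
                              cutpoints = NULL,
                              pgy = 5L,
                              complexity = "average",
                              missing_rate = 0,
                              seed = 1L) {
  as_sigma <- function(x, nm) {
    if (length(x) == 1L) x <- diag(as.numeric(x), 4)
    x <- as.matrix(x)
    if (!all(dim(x) == c(4L, 4L)))
      stop(sprintf("%s must be a 4x4 matrix", nm), call. = FALSE)
    if (max(abs(x - t(x))) > 1e-8 * max(1, max(abs(x))))
      stop(sprintf("%s must be symmetric", nm), call. = FALSE)
    x <- (x + t(x)) / 2
    if (any(diag(x) < 0))
      stop(sprintf("%s has a negative diagonal entry", nm), call. = FALSE)
    ev <- eigen(x, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8 * max(1, max(abs(ev))))
      stop(sprintf("%s is not positive semidefinite (min eigenvalue %.3g)",
                   nm, min(ev)), call. = FALSE)
    dimnames(x) <- list(SCORE_VARS, SCORE_VARS)
    x
  }
  n_trainees <- as.integer(n_trainees)
  n_procedures <- as.integer(n_procedures)
  procedures_per_trainee <- as.integer(procedures_per_trainee)
  stopifnot(n_trainees >= 1L, n_procedures >= 1L,
            procedures_per_trainee >= 0L)
  if (procedures_per_trainee > n_procedures)
    stop("procedures_per_trainee cannot exceed n_procedures", call. = FALSE)
  stopifnot(length(grand_means) == 4L, is.numeric(grand_means))
  if (!is.null(cutpoints)) {
    stopifnot(is.list(cutpoints), length(cutpoints) == 4L)
    for (v in seq_len(4L)) {
      cp <- cutpoints[[v]]
      need <- SCORE_LEVELS[[v]] - 1L
      if (length(cp) != need || any(diff(cp) <= 0))
        stop(sprintf(
          "cutpoints for %s must be %d strictly increasing values",
          SCORE_VARS[v], need), call. = FALSE)
    }
  }
  stopifnot(missing_rate >= 0, missing_rate < 1)
  complexity <- match.arg(complexity, COMPLEXITY_LEVELS)
  pgy <- as.integer(pgy)
  stopifnot(pgy >= 1L, pgy <= 5L)

  structure(list(
    n_trainees = n_trainees,
    n_procedures = n_procedures,
    procedures_per_trainee = procedures_per_trainee,
    sigma_t = as_sigma(sigma_t, "sigma_t"),
    sigma_p = as_sigma(sigma_p, "sigma_p"),
    sigma_tp = as_sigma(sigma_tp, "sigma_tp"),
    grand_means = as.numeric(grand_means),
    cutpoints = cutpoints,
    pgy = pgy,
    complexity = complexity,
    missing_rate = missing_rate,
    seed = as.integer(seed)
  ), class = "simulation_config")
}

#' Illustrative ground-truth components for a senior-resident stratum
#'
#' Default generating components whose variance magnitudes follow published
#' senior-resident (PGY 5) operative-rating analyses: trainee variance is
#' modest, procedure variance small, and the trainee-by-procedure interaction
#' dominates.  Off-diagonal structure (true-score correlation ~0.87 between
#' the two autonomy ratings, ~0.45 between the two performance ratings,
#' weaker cross-item and interaction correlations) is illustrative, not
#' calibrated: raw multi-institution rating data is not public.
#'
#' @return List with `sigma_t`, `sigma_p`, `sigma_tp` (4x4 matrices) and
#'   `grand_means` (length 4), in the order of [score_variables()].
#' @export
senior_truth <- function() {
  cor_to_cov <- function(d, R) {
    s <- sqrt(d)
    out <- R * tcrossprod(s)
    dimnames(out) <- list(SCORE_VARS, SCORE_VARS)
    out
  }
  corr_t <- matrix(c(1, 0.87, 0.60, 0.55,
                     0.87, 1, 0.55, 0.60,
                     0.60, 0.55, 1, 0.45,
                     0.55, 0.60, 0.45, 1), 4, 4)
  corr_p <- matrix(c(1, 0.5, 0.3, 0.3,
                     0.5, 1, 0.3, 0.3,
                     0.3, 0.3, 1, 0.5,
                     0.3, 0.3, 0.5, 1), 4, 4)
  corr_e <- matrix(c(1, 0.3, 0.4, 0.2,
                     0.3, 1, 0.2, 0.4,
                     0.4, 0.2, 1, 0.3,
                     0.2, 0.4, 0.3, 1), 4, 4)
  list(
    sigma_t = cor_to_cov(c(0.064, 0.090, 0.033, 0.097), corr_t),
    sigma_p = cor_to_cov(c(0.041, 0.084, 0.013, 0.017), corr_p),
    sigma_tp = cor_to_cov(c(0.317, 0.312, 0.222, 0.152), corr_e),
    grand_means = c(3.35, 3.16, 3.98, 3.65)
  )
}

#' Default latent thresholds for ordinal output
#'
#' Equal-width cutpoints centred so that latent scores near the grand means
#' map onto the middle of each ordinal scale: autonomy items are cut at
#' 1.5, 2.5, 3.5; performance items at 1.5, 2.5, 3.5, 4.5.  With latent
#' scores generated on the rating scale itself this reproduces simple
#' rounding to the nearest legal level (clamped at the ends).
#'
#' @return List of four cutpoint vectors in the order of [score_variables()].
#' @export
default_cutpoints <- function() {
  list(score_fa = c(1.5, 2.5, 3.5),
       score_ta = c(1.5, 2.5, 3.5),
       score_fp = c(1.5, 2.5, 3.5, 4.5),
       score_tp = c(1.5, 2.5, 3.5, 4.5))
}

## MVN sampler tolerant of semidefinite (including zero) covariance.
rmvn_psd <- function(n, sigma) {
  ev <- eigen(sigma, symmetric = TRUE)
  lam <- pmax(ev$values, 0)
  z <- matrix(rnorm(n * ncol(sigma)), n, ncol(sigma))
  z %*% (t(ev$vectors) * sqrt(lam))
}

discretize_scores <- function(x, cutpoints) {
  ## level k iff x in (c[k-1], c[k]]; c[0] = -Inf, c[K] = Inf
  k <- rep(1L, length(x))
  for (cp in cutpoints) k <- k + as.integer(x > cp)
  k
}

#' Generate a synthetic assessment table with known components
#'
#' Draws trainee, procedure, and interaction effect vectors from multivariate
#' normal distributions with the configured covariance components, links each
#' trainee to a set of procedures, and emits one score vector per realized
#' (trainee, procedure) cell:
#' `score = grand_means + t_i + p_j + e_ij`.  With cutpoints set, each latent
#' variable is discretized by threshold crossing; rows are then removed
#' independently with probability `missing_rate`.
#'
#' @param config A [simulation_config()].
#' @return A `data.frame` assessment table with columns `trainee_id`,
#'   `procedure_id`, `pgy`, `complexity`, and the four score columns, at most
#'   one row per (trainee, procedure).
#' @examples
#' cfg <- simulation_config(n_trainees = 20, n_procedures = 5, seed = 7)
#' head(generate_dataset(cfg))
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  nt <- config$n_trainees
  np <- config$n_procedures
  ppt <- config$procedures_per_trainee

  t_eff <- rmvn_psd(nt, config$sigma_t)
  p_eff <- rmvn_psd(np, config$sigma_p)

  if (ppt == 0L) {
    ti <- rep(seq_len(nt), each = np)
    pj <- rep(seq_len(np), times = nt)
  } else {
    ti <- rep(seq_len(nt), each = ppt)
    pj <- unlist(lapply(seq_len(nt), function(i) {
      sort(sample.int(np, ppt, replace = FALSE))
    }), use.names = FALSE)
  }
  ncell <- length(ti)
  e_eff <- rmvn_psd(ncell, config$sigma_tp)

  scores <- matrix(config$grand_means, ncell, 4, byrow = TRUE) +
    t_eff[ti, , drop = FALSE] + p_eff[pj, , drop = FALSE] + e_eff
  colnames(scores) <- SCORE_VARS

  if (!is.null(config$cutpoints)) {
    for (v in seq_len(4L))
      scores[, v] <- discretize_scores(scores[, v], config$cutpoints[[v]])
  }

  keep <- if (config$missing_rate > 0)
    runif(ncell) >= config$missing_rate else rep(TRUE, ncell)

  out <- data.frame(
    trainee_id = sprintf("T%04d", ti[keep]),
    procedure_id = sprintf("P%03d", pj[keep]),
    pgy = config$pgy,
    complexity = config$complexity,
    stringsAsFactors = FALSE
  )
  out <- cbind(out, as.data.frame(scores[keep, , drop = FALSE]))
  rownames(out) <- NULL
  out
}
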