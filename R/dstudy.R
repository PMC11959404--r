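## Composite D studies: project G-study components onto designs with n_p
## procedures.  The rater and item facets are fixed and enter only through
## the composite weights; the procedure facet is random.

#' Composite weights over the four score variables
#'
#' Nonnegative weights in the order of [score_variables()], normalized to sum
#' to one on construction.  The default is equal weighting (1/4 each), which
#' treats the two raters and two items symmetrically.
#'
#' @param w Length-4 nonnegative vector; need not sum to 1.
#' @return Object of class `composite_weights` (a normalized numeric vector).
#' @export
composite_weights <- function(w = rep(1, 4)) {
  stopifnot(is.numeric(w), length(w) == 4L, all(w >= 0), sum(w) > 0)
  structure(setNames(w / sum(w), SCORE_VARS), class = "composite_weights")
}

#' Composite D study at a fixed number of procedures
#'
#' With composite weights `w` and G-study components, the composite
#' universe-score variance is `s2_tau = w' S_t w`; averaging over `n_p`
#' procedures gives relative error `s2_delta = w' S_tp w / n_p` and absolute
#' error `s2_Delta = w' (S_p + S_tp) w / n_p`.  The generalizability
#' coefficient is `Erho2 = s2_tau / (s2_tau + s2_delta)` (norm-referenced)
#' and the index of dependability `Phi = s2_tau / (s2_tau + s2_Delta)`
#' (criterion-referenced); `SEM = sqrt(s2_Delta)`.
#'
#' Two confidence margins are emitted: `ci95_margin_paper = 1 * SEM`, the
#' convention used in the source analyses this package mirrors, and
#' `ci95_margin_normal = 1.96 * SEM`, the conventional normal-theory 95%
#' half-width.
#'
#' @param components A [gstudy_components()] object.
#' @param weights A [composite_weights()] object (default equal weights).
#' @param n_p Number of procedures in the decision design (integer >= 1).
#' @return Object of class `dstudy_result`: a list with fields `n_p`,
#'   `universe_score_variance`, `relative_error_variance`,
#'   `absolute_error_variance`, `gen_coefficient`, `dependability`,
#'   `sem_absolute`, `ci95_margin_paper`, `ci95_margin_normal`.  Reliability
#'   coefficients are `NA` (with a warning) when both universe-score and
#'   error variance vanish.
#' @export
composite_dstudy <- function(components, weights = composite_weights(),
                             n_p) {
  stopifnot(inherits(components, "gstudy_components"),
            inherits(weights, "composite_weights"))
  n_p <- as.integer(n_p)
  stopifnot(length(n_p) == 1L, n_p >= 1L)
  w <- as.numeric(weights)
  s2_tau <- drop(w %*% components$sigma_t %*% w)
  s2_delta <- drop(w %*% components$sigma_tp %*% w) / n_p
  s2_Delta <- drop(w %*% (components$sigma_p + components$sigma_tp) %*% w) /
    n_p
  warned <- FALSE
  ratio <- function(err) {
    if (s2_tau + err <= 0) {
      if (!warned) {
        warning("universe-score and error variance both zero; ",
                "reliability undefined", call. = FALSE)
        warned <<- TRUE
      }
      NA_real_
    } else s2_tau / (s2_tau + err)
  }
  sem <- sqrt(s2_Delta)
  structure(list(
    n_p = n_p,
    universe_score_variance = s2_tau,
    relative_error_variance = s2_delta,
    absolute_error_variance = s2_Delta,
    gen_coefficient = ratio(s2_delta),
    dependability = ratio(s2_Delta),
    sem_absolute = sem,
    ci95_margin_paper = sem,
    ci95_margin_normal = 1.96 * sem
  ), class = "dstudy_result")
}

#' @export
print.dstudy_result <- function(x, ...) {
  cat(sprintf(
    paste0("Composite D study (n_p = %d)\n",
           "  universe score variance: %.3f\n",
           "  relative error variance: %.3f\n",
           "  absolute error variance: %.3f\n",
           "  generalizability coefficient (Erho2): %.3f\n",
           "  index of dependability (Phi): %.3f\n",
           "  SEM (absolute): %.2f\n"),
    x$n_p, x$universe_score_variance, x$relative_error_variance,
    x$absolute_error_variance, x$gen_coefficient, x$dependability,
    x$sem_absolute))
  invisible(x)
}

#' SEM-based score margin
#'
#' One standard error of measurement, `sqrt(absolute error variance)`,
#' rounded for report display.  Note this matches the +/- margins printed in
#' the analyses this package mirrors; a conventional normal-theory 95%
#' interval would use 1.96 SEM.
#'
#' @param absolute_error_variance Nonnegative variance.
#' @param digits Rounding (default 2 decimals, rating-scale units).
#' @return The rounded margin.
#' @export
sem_margin <- function(absolute_error_variance, digits = 2) {
  if (any(absolute_error_variance < 0))
    stop("absolute_error_variance must be nonnegative", call. = FALSE)
  round(sqrt(absolute_error_variance), digits)
}

#' Minimum number of procedures reaching a reliability threshold
#'
#' Both coefficients are monotone nondecreasing in `n_p`, so the smallest
#' `n_p` in `[1, n_max]` with `criterion(n_p) >= threshold` is found by
#' bisection.  For the index of dependability the closed form is
#' `n* = ceil( threshold/(1-threshold) * w'(S_p + S_tp)w / s2_tau )`.
#'
#' @param components A [gstudy_components()] object.
#' @param weights A [composite_weights()] object.
#' @param threshold Reliability threshold in (0, 1) (conventionally 0.8).
#' @param criterion `"dependability"` (Phi) or `"generalizability"` (Erho2).
#' @param n_max Largest design size to consider.
#' @return Integer `n*`, or `NA_integer_` (with attribute
#'   `reason = "not attainable"` and a warning) when the threshold is not
#'   reached by `n_max` — in particular whenever the composite universe-score
#'   variance is zero.
#' @export
min_procedures <- function(components, weights = composite_weights(),
                           threshold = 0.8,
                           criterion = c("dependability",
                                         "generalizability"),
                           n_max = 100L) {
  criterion <- match.arg(criterion)
  stopifnot(threshold > 0, threshold < 1, n_max >= 1L)
  coef_at <- function(n) {
    d <- composite_dstudy(components, weights, n)
    if (criterion == "dependability") d$dependability else d$gen_coefficient
  }
  top <- coef_at(n_max)
  if (is.na(top) || top < threshold) {
    warning("threshold ", threshold, " not attainable within n_max = ",
            n_max, call. = FALSE)
    return(structure(NA_integer_, reason = "not attainable"))
  }
  lo <- 1L; hi <- as.integer(n_max)
  while (lo < hi) {
    mid <- (lo + hi) %/% 2L
    if (coef_at(mid) >= threshold) hi <- mid else lo <- mid + 1L
  }
  lo
}

#' D-study curve over a range of design sizes
#'
#' @param components A [gstudy_components()] object.
#' @param weights A [composite_weights()] object.
#' @param n_range Increasing vector of positive integers.
#' @return `data.frame` with one row per `n_p`: error variances, Erho2, Phi,
#'   and SEM.  Phi and Erho2 are nondecreasing and SEM nonincreasing in
#'   `n_p`; `SEM * sqrt(n_p)` is constant along the curve.
#' @export
dstudy_curve <- function(components, weights = composite_weights(),
                         n_range = 1:20) {
  stopifnot(length(n_range) >= 1L, all(diff(n_range) > 0),
            all(n_range >= 1))
  rows <- lapply(n_range, function(n) {
    d <- composite_dstudy(components, weights, n)
    data.frame(n_p = d$n_p,
               universe_score_variance = d$universe_score_variance,
               relative_error_variance = d$relative_error_variance,
               absolute_error_variance = d$absolute_error_variance,
               gen_coefficient = d$gen_coefficient,
               dependability = d$dependability,
               sem_absolute = d$sem_absolute)
  })
  do.call(rbind, rows)
}
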