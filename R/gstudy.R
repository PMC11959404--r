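## Multivariate G study for the trainees x procedures design with four
## fixed-facet score variables.  One observation per cell, so the
## trainee-by-procedure interaction and the residual are confounded in a
## single tp component.

#' G-study variance/covariance components
#'
#' Container for the three 4x4 covariance-component matrices of the
#' trainees (t), procedures (p), and trainee-by-procedure (tp) effects, in
#' the fixed variable order of [score_variables()].  On construction each
#' matrix is symmetrized; negative diagonal entries are truncated to zero and
#' off-diagonals clipped so that `|cov| <= sqrt(var_u * var_v)` (standard
#' reporting practice for variance-component estimates).  The untruncated
#' estimates are retained in `attr(x, "raw")`.
#'
#' @param sigma_t,sigma_p,sigma_tp 4x4 matrices of component estimates.
#' @param n_trainees,n_procedures_mean Design bookkeeping: number of trainees
#'   and (mean) number of procedures per trainee.
#' @param estimator `"balanced-EMS"` or `"unbalanced-REML"`.
#' @return Object of class `gstudy_components`.
#' @export
gstudy_components <- function(sigma_t, sigma_p, sigma_tp,
                              n_trainees = NA_integer_,
                              n_procedures_mean = NA_real_,
                              estimator = c("balanced-EMS",
                                            "unbalanced-REML")) {
  estimator <- match.arg(estimator)
  fix <- function(m) {
    m <- (as.matrix(m) + t(as.matrix(m))) / 2
    dimnames(m) <- list(SCORE_VARS, SCORE_VARS)
    m
  }
  raw <- list(sigma_t = fix(sigma_t), sigma_p = fix(sigma_p),
              sigma_tp = fix(sigma_tp))
  truncate <- function(m) {
    d <- pmax(diag(m), 0)
    bound <- sqrt(outer(d, d))
    m <- sign(m) * pmin(abs(m), bound)
    diag(m) <- d
    m
  }
  out <- structure(list(
    sigma_t = truncate(raw$sigma_t),
    sigma_p = truncate(raw$sigma_p),
    sigma_tp = truncate(raw$sigma_tp),
    n_trainees = n_trainees,
    n_procedures_mean = n_procedures_mean,
    estimator = estimator
  ), class = "gstudy_components")
  attr(out, "raw") <- raw
  out
}

#' @export
print.gstudy_components <- function(x, digits = 3, ...) {
  cat(sprintf("G-study components (%s; %s trainees, mean %.1f procedures)\n",
              x$estimator, x$n_trainees, x$n_procedures_mean))
  for (nm in c("sigma_t", "sigma_p", "sigma_tp")) {
    cat("\n", nm, ":\n", sep = "")
    print(round(x[[nm]], digits))
  }
  invisible(x)
}

is_crossed_balanced <- function(table) {
  nt <- length(unique(table$trainee_id))
  np <- length(unique(table$procedure_id))
  nrow(table) == nt * np
}

#' Balanced multivariate G study (expected mean squares)
#'
#' Closed-form ANOVA estimator for a fully crossed trainees x procedures
#' design with one observation per cell.  For every variable pair, mean
#' squares/cross-products are formed from trainee marginal means, procedure
#' marginal means, and the interaction residual, and the expected-mean-square
#' equations are solved:
#' `sigma_tp = MS_tp`, `sigma_t = (MS_t - MS_tp) / n_p`,
#' `sigma_p = (MS_p - MS_tp) / n_t`.
#'
#' @param table Fully crossed assessment data.frame (every trainee rated on
#'   every procedure), with at least 2 trainees and 2 procedures.
#' @return A [gstudy_components()] object.
#' @export
estimate_balanced <- function(table) {
  validate_assessments(table)
  if (!is_crossed_balanced(table))
    stop("table is not fully crossed and balanced; use estimate_unbalanced()",
         call. = FALSE)
  tid <- factor(table$trainee_id)
  pid <- factor(table$procedure_id)
  nt <- nlevels(tid)
  np <- nlevels(pid)
  if (nt < 2L || np < 2L)
    stop("need at least 2 trainees and 2 procedures", call. = FALSE)

  y <- as.matrix(table[SCORE_VARS])
  m_t <- rowsum(y, tid) / np            # trainee marginal means, nt x 4
  m_p <- rowsum(y, pid) / nt            # procedure marginal means, np x 4
  g <- colMeans(y)

  mscp_t <- np * crossprod(sweep(m_t, 2, g)) / (nt - 1)
  mscp_p <- nt * crossprod(sweep(m_p, 2, g)) / (np - 1)
  resid <- y - m_t[tid, , drop = FALSE] - m_p[pid, , drop = FALSE] +
    matrix(g, nrow(y), 4, byrow = TRUE)
  mscp_tp <- crossprod(resid) / ((nt - 1) * (np - 1))

  gstudy_components(
    sigma_t = (mscp_t - mscp_tp) / np,
    sigma_p = (mscp_p - mscp_tp) / nt,
    sigma_tp = mscp_tp,
    n_trainees = nt,
    n_procedures_mean = np,
    estimator = "balanced-EMS"
  )
}

## Connectivity of the trainee-procedure incidence graph (label propagation).
incidence_components <- function(trainee, procedure) {
  tid <- as.integer(factor(trainee))
  pid <- as.integer(factor(procedure))
  lab_t <- seq_len(max(tid))
  lab_p <- rep(0L, max(pid))
  repeat {
    new_p <- tapply(lab_t[tid], pid, min)
    lab_p2 <- lab_p
    lab_p2[as.integer(names(new_p))] <- new_p
    new_t <- tapply(lab_p2[pid], tid, min)
    lab_t2 <- lab_t
    lab_t2[as.integer(names(new_t))] <- pmin(lab_t[as.integer(names(new_t))],
                                             new_t)
    if (identical(lab_t2, lab_t) && identical(lab_p2, lab_p)) break
    lab_t <- lab_t2
    lab_p <- lab_p2
  }
  length(unique(lab_t))
}

reml_varcomp <- function(y, data) {
  ## Two-way crossed random-effects fit, y = mu + t_i + p_j + e_ij, REML.
  ## Tight optimizer tolerances so that balanced data reproduces the ANOVA
  ## solution to ~1e-8 relative.
  df <- data.frame(y = y, trainee_id = data$trainee_id,
                   procedure_id = data$procedure_id)
  ctrl <- lme4::lmerControl(
    optimizer = "nloptwrap",
    optCtrl = list(xtol_abs = 1e-12, ftol_abs = 1e-14,
                   xtol_rel = 1e-12, ftol_rel = 1e-14, maxeval = 100000),
    calc.derivs = FALSE,
    check.conv.singular = "ignore")
  fit <- suppressWarnings(suppressMessages(
    lme4::lmer(y ~ 1 + (1 | trainee_id) + (1 | procedure_id),
               data = df, REML = TRUE, control = ctrl)))
  vc <- as.data.frame(lme4::VarCorr(fit))
  get <- function(grp) vc$vcov[vc$grp == grp]
  c(t = get("trainee_id"), p = get("procedure_id"), tp = get("Residual"))
}

#' Unbalanced multivariate G study (REML)
#'
#' Variance components for each of the four variables are estimated by
#' restricted maximum likelihood for the two-way crossed random-effects model
#' with missing cells (procedures crossed with trainees, not nested: a
#' separate procedure component is identified through procedures shared
#' across trainees).  Covariance components are recovered from pairwise
#' sum/difference fits: for variables u and v the same model is fitted to
#' `y_u + y_v` and `y_u - y_v`, and per effect
#' `cov(u, v) = (var_sum - var_diff) / 4`.  On balanced data this reproduces
#' [estimate_balanced()] to optimizer precision (~1e-8 relative).
#'
#' @param table Assessment data.frame; each trainee needs >= 1 procedure and
#'   the design must include >= 2 distinct procedures.  A disconnected
#'   trainee-procedure incidence graph triggers an identifiability warning.
#' @return A [gstudy_components()] object.
#' @export
estimate_unbalanced <- function(table) {
  validate_assessments(table)
  np_distinct <- length(unique(table$procedure_id))
  if (np_distinct < 2L)
    stop("degenerate stratum: only ", np_distinct,
         " distinct procedure(s); procedure variance is not identifiable",
         call. = FALSE)
  ncomp <- incidence_components(table$trainee_id, table$procedure_id)
  if (ncomp > 1L)
    warning("trainee-procedure incidence graph has ", ncomp,
            " connected components; variance components may be weakly ",
            "identified", call. = FALSE)

  y <- as.matrix(table[SCORE_VARS])
  sig <- list(t = matrix(0, 4, 4), p = matrix(0, 4, 4), tp = matrix(0, 4, 4))
  for (u in seq_len(4L)) {
    vc <- reml_varcomp(y[, u], table)
    for (eff in names(sig)) sig[[eff]][u, u] <- vc[[eff]]
  }
  for (u in seq_len(3L)) for (v in seq.int(u + 1L, 4L)) {
    vc_sum <- reml_varcomp(y[, u] + y[, v], table)
    vc_diff <- reml_varcomp(y[, u] - y[, v], table)
    for (eff in names(sig)) {
      cov_uv <- (vc_sum[[eff]] - vc_diff[[eff]]) / 4
      sig[[eff]][u, v] <- sig[[eff]][v, u] <- cov_uv
    }
  }
  gstudy_components(
    sigma_t = sig$t, sigma_p = sig$p, sigma_tp = sig$tp,
    n_trainees = length(unique(table$trainee_id)),
    n_procedures_mean = nrow(table) / length(unique(table$trainee_id)),
    estimator = "unbalanced-REML"
  )
}

#' Variance proportions for one score variable
#'
#' Shares of total variance attributed to the trainee, procedure, and
#' interaction effects, as percentages summing to 100.
#'
#' @param components A [gstudy_components()] object.
#' @param variable Variable index 1-4 or name from [score_variables()].
#' @param digits Rounding for reporting (default 1 decimal); `NA` for
#'   unrounded values.
#' @return Named numeric vector `c(t =, p =, tp =)` of percentages.
#' @export
proportion_table <- function(components, variable, digits = 1) {
  stopifnot(inherits(components, "gstudy_components"))
  if (is.character(variable)) variable <- match(variable, SCORE_VARS)
  stopifnot(variable %in% 1:4)
  v <- c(t = components$sigma_t[variable, variable],
         p = components$sigma_p[variable, variable],
         tp = components$sigma_tp[variable, variable])
  total <- sum(v)
  if (total <= 0)
    stop("total variance for ", SCORE_VARS[variable],
         " is zero; proportions undefined", call. = FALSE)
  out <- 100 * v / total
  if (!is.na(digits)) out <- round(out, digits)
  out
}
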