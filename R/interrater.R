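## Faculty-trainee agreement: role means and the dis-attenuated correlation
## of universe (true) scores, per item.

ITEM_VARS <- list(autonomy = c("score_fa", "score_ta"),
                  performance = c("score_fp", "score_tp"))

#' Dis-attenuated faculty-trainee correlation for one item
#'
#' Correlation of the universe (true) scores of the faculty and trainee
#' ratings of an item, computed directly from the trainee-effect covariance
#' component: `rho = S_t[u, v] / sqrt(S_t[u, u] * S_t[v, v])`.  Unlike the
#' raw Pearson correlation of observed scores, this is free of attenuation
#' from procedure sampling and interaction noise.  Noisy component estimates
#' can land outside `[-1, 1]`; such values are clipped with a warning (the
#' raw value is kept in `attr(x, "raw")`).
#'
#' @param components A [gstudy_components()] object.
#' @param item `"autonomy"` or `"performance"`.
#' @return Dis-attenuated correlation in `[-1, 1]`.  Zero universe-score
#'   variance in either rating makes the correlation undefined (error).
#' @export
disattenuated_correlation <- function(components,
                                      item = c("autonomy", "performance")) {
  stopifnot(inherits(components, "gstudy_components"))
  item <- match.arg(item)
  uv <- match(ITEM_VARS[[item]], SCORE_VARS)
  st <- components$sigma_t
  vu <- st[uv[1], uv[1]]
  vv <- st[uv[2], uv[2]]
  if (vu <= 0 || vv <= 0)
    stop("universe-score variance is zero for a ", item,
         " rating; dis-attenuated correlation undefined", call. = FALSE)
  r <- st[uv[1], uv[2]] / sqrt(vu * vv)
  out <- r
  if (abs(r) > 1) {
    warning("dis-attenuated correlation ", format(round(r, 3)),
            " outside [-1, 1]; clipped", call. = FALSE)
    out <- sign(r)
  }
  structure(out, raw = r)
}

#' Raw Pearson correlation of observed faculty/trainee scores
#'
#' Classical comparator for [disattenuated_correlation()]: attenuated toward
#' zero by procedure-sampling and interaction error.
#'
#' @param table Assessment data.frame.
#' @param item `"autonomy"` or `"performance"`.
#' @return Pearson correlation of the two observed score columns.
#' @export
observed_correlation <- function(table,
                                 item = c("autonomy", "performance")) {
  item <- match.arg(item)
  uv <- ITEM_VARS[[item]]
  cor(table[[uv[1]]], table[[uv[2]]])
}

#' Mean ratings by rater role and item
#'
#' @param table Nonempty assessment data.frame.
#' @return `data.frame` with columns `item` (autonomy, performance), `role`
#'   (faculty, trainee), and `mean` (arithmetic mean on the rating scale).
#' @export
role_means <- function(table) {
  validate_assessments(table)
  data.frame(
    item = rep(c("autonomy", "performance"), each = 2),
    role = rep(c("faculty", "trainee"), times = 2),
    mean = c(mean(table$score_fa), mean(table$score_ta),
             mean(table$score_fp), mean(table$score_tp))
  )
}

#' Faculty-trainee agreement summary for one stratum
#'
#' @param table Assessment data.frame for one stratum.
#' @param components Matching [gstudy_components()] estimates.
#' @return `data.frame` with one row per item: faculty mean, trainee mean,
#'   dis-attenuated correlation, and the raw observed correlation.
#' @export
interrater_table <- function(table, components) {
  rm <- role_means(table)
  one <- function(item) {
    rho <- tryCatch(as.numeric(disattenuated_correlation(components, item)),
                    error = function(e) NA_real_)
    data.frame(
      item = item,
      mean_faculty = rm$mean[rm$item == item & rm$role == "faculty"],
      mean_trainee = rm$mean[rm$item == item & rm$role == "trainee"],
      disattenuated_r = rho,
      observed_r = observed_correlation(table, item)
    )
  }
  rbind(one("autonomy"), one("performance"))
}
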