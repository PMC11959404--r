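## Shared fixtures and independent oracles.  The EMS oracle evaluates the
## expected-mean-square identities by naive double-loop summation and is
## kept independent of the package's matrix-algebra implementation.

SV <- score_variables()

## Build a crossed assessment table from one nt x np matrix per variable
## (a single matrix is recycled to all four variables).
grid_table <- function(..., pgy = 5L, complexity = "average") {
  mats <- list(...)
  if (length(mats) == 1L) mats <- rep(mats, 4L)
  stopifnot(length(mats) == 4L)
  nt <- nrow(mats[[1]]); np <- ncol(mats[[1]])
  out <- data.frame(
    trainee_id = sprintf("T%04d", rep(seq_len(nt), each = np)),
    procedure_id = sprintf("P%03d", rep(seq_len(np), times = nt)),
    pgy = pgy, complexity = complexity)
  for (v in seq_len(4L)) out[[SV[v]]] <- as.vector(t(mats[[v]]))
  out
}

## Brute-force multivariate EMS oracle for a balanced crossed design:
## untruncated component estimates via direct summation.
oracle_ems <- function(table) {
  tid <- sort(unique(table$trainee_id))
  pid <- sort(unique(table$procedure_id))
  nt <- length(tid); np <- length(pid)
  arr <- array(NA_real_, c(nt, np, 4))
  for (r in seq_len(nrow(table))) {
    i <- match(table$trainee_id[r], tid)
    j <- match(table$procedure_id[r], pid)
    for (v in 1:4) arr[i, j, v] <- table[[SV[v]]][r]
  }
  stopifnot(!anyNA(arr))
  g <- apply(arr, 3, mean)
  sig <- list(sigma_t = matrix(0, 4, 4), sigma_p = matrix(0, 4, 4),
              sigma_tp = matrix(0, 4, 4))
  for (u in 1:4) for (v in 1:4) {
    s_t <- 0; s_p <- 0; s_tp <- 0
    for (i in 1:nt) {
      mu_i_u <- mean(arr[i, , u]); mu_i_v <- mean(arr[i, , v])
      s_t <- s_t + np * (mu_i_u - g[u]) * (mu_i_v - g[v])
    }
    for (j in 1:np) {
      mu_j_u <- mean(arr[, j, u]); mu_j_v <- mean(arr[, j, v])
      s_p <- s_p + nt * (mu_j_u - g[u]) * (mu_j_v - g[v])
    }
    for (i in 1:nt) for (j in 1:np) {
      r_u <- arr[i, j, u] - mean(arr[i, , u]) - mean(arr[, j, u]) + g[u]
      r_v <- arr[i, j, v] - mean(arr[i, , v]) - mean(arr[, j, v]) + g[v]
      s_tp <- s_tp + r_u * r_v
    }
    ms_t <- s_t / (nt - 1)
    ms_p <- s_p / (np - 1)
    ms_tp <- s_tp / ((nt - 1) * (np - 1))
    sig$sigma_tp[u, v] <- ms_tp
    sig$sigma_t[u, v] <- (ms_t - ms_tp) / np
    sig$sigma_p[u, v] <- (ms_p - ms_tp) / nt
  }
  sig
}

## Untruncated estimates of a gstudy_components object.
raw_components <- function(cp) attr(cp, "raw")

balanced_fixture_small <- function(seed = 5) {
  generate_dataset(simulation_config(n_trainees = 5, n_procedures = 4,
                                     seed = seed))
}

## Ground truth with dominant interaction noise and known trainee-effect
## correlation between the two autonomy ratings.
agreement_truth <- function(rho_t = 0.7) {
  sigma_t <- diag(c(0.09, 0.09, 0.06, 0.06))
  sigma_t[1, 2] <- sigma_t[2, 1] <- rho_t * 0.09
  list(sigma_t = sigma_t,
       sigma_p = diag(c(0.02, 0.02, 0.02, 0.02)),
       sigma_tp = {
         s <- diag(c(0.5, 0.5, 0.4, 0.4))
         s[1, 2] <- s[2, 1] <- 0.1
         s
       })
}
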