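test_that("constant table yields exactly zero components", {
  m <- matrix(3, 4, 5)
  cp <- estimate_balanced(grid_table(m))
  expect_equal(cp$sigma_t, matrix(0, 4, 4), ignore_attr = TRUE)
  expect_equal(cp$sigma_p, matrix(0, 4, 4), ignore_attr = TRUE)
  expect_equal(cp$sigma_tp, matrix(0, 4, 4), ignore_attr = TRUE)
})

test_that("3x3 grid with trainee means (1,2,3) matches the EMS oracle", {
  m <- matrix(rep(1:3, each = 3), 3, 3, byrow = TRUE)  # rows = trainees
  tab <- grid_table(m, matrix(3, 3, 3), matrix(3, 3, 3), matrix(3, 3, 3))
  cp <- estimate_balanced(tab)
  orc <- oracle_ems(tab)
  ## trainee means 1,2,3, no procedure or interaction variability:
  ## MS_t = 3 * var(1:3) = 3, sigma_t = 3 / n_p = 1
  expect_equal(cp$sigma_t[1, 1], 1)
  expect_equal(cp$sigma_p[1, 1], 0)
  expect_equal(cp$sigma_tp[1, 1], 0)
  expect_equal(raw_components(cp)$sigma_t, orc$sigma_t, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("balanced estimator matches the brute-force oracle on random grids", {
  set.seed(2024)
  for (rep in 1:12) {
    nt <- sample(3:6, 1); np <- sample(3:6, 1)
    mats <- replicate(4, matrix(rnorm(nt * np, mean = 3), nt, np),
                      simplify = FALSE)
    tab <- do.call(grid_table, mats)
    raw <- raw_components(estimate_balanced(tab))
    orc <- oracle_ems(tab)
    for (nm in names(orc))
      expect_equal(raw[[nm]], orc[[nm]], tolerance = 1e-10,
                   ignore_attr = TRUE)
  }
})

test_that("components are translation invariant and scale equivariant", {
  set.seed(7)
  mats <- replicate(4, matrix(rnorm(20, 3), 4, 5), simplify = FALSE)
  tab <- do.call(grid_table, mats)
  base <- raw_components(estimate_balanced(tab))

  shifted <- tab
  shifted$score_ta <- shifted$score_ta + 10
  expect_equal(raw_components(estimate_balanced(shifted)), base,
               tolerance = 1e-9)

  scaled <- tab
  scaled$score_fa <- scaled$score_fa * 2
  raw2 <- raw_components(estimate_balanced(scaled))
  for (nm in names(base)) {
    expect_equal(raw2[[nm]][1, 1], 4 * base[[nm]][1, 1], tolerance = 1e-9)
    expect_equal(raw2[[nm]][1, 2:4], 2 * base[[nm]][1, 2:4],
                 tolerance = 1e-9)
    expect_equal(raw2[[nm]][2:4, 2:4], base[[nm]][2:4, 2:4],
                 tolerance = 1e-9)
  }
})

test_that("truncation clips negative variances and bounds covariances", {
  cp <- gstudy_components(
    sigma_t = matrix(c(-0.02, 0.5, 0.5, 0.01), 2, 2)[c(1, 1, 2, 2),
                                                     c(1, 1, 2, 2)],
    sigma_p = diag(0.01, 4), sigma_tp = diag(0.2, 4))
  expect_true(all(diag(cp$sigma_t) >= 0))
  d <- diag(cp$sigma_t)
  expect_true(all(abs(cp$sigma_t) <= sqrt(outer(d, d)) + 1e-12))
  expect_lt(raw_components(cp)$sigma_t[1, 1], 0)  # raw value retained
})

test_that("estimator dispatch errors are informative", {
  tab <- balanced_fixture_small()
  expect_error(estimate_balanced(tab[-1, ]), "estimate_unbalanced")
  one_proc <- tab[tab$procedure_id == tab$procedure_id[1], ]
  expect_error(estimate_unbalanced(one_proc), "identifiable")
})

test_that("REML recovers components after balanced thinning", {
  ## unbalanced recovery: truth -> crossed data -> thin to 3/trainee -> REML
  tr <- senior_truth()
  cfg <- simulation_config(n_trainees = 250, n_procedures = 10,
                           sigma_t = tr$sigma_t, sigma_p = tr$sigma_p,
                           sigma_tp = tr$sigma_tp,
                           grand_means = tr$grand_means, seed = 31)
  thin <- sample_balanced(generate_dataset(cfg),
                          sampling_config(3, 50, seed = 32))
  cp <- estimate_unbalanced(thin)
  ## loose Monte-Carlo tolerances: 250 trainees x 3 procedures
  expect_equal(diag(cp$sigma_tp), diag(tr$sigma_tp), tolerance = 0.25,
               ignore_attr = TRUE)
  expect_lt(max(abs(diag(cp$sigma_t) - diag(tr$sigma_t))), 0.06)
  expect_lt(max(abs(diag(cp$sigma_p) - diag(tr$sigma_p))), 0.08)
})

test_that("sum/difference covariance recovery finds a known cov(t)", {
  sigma_t <- diag(c(0.10, 0.10, 0.05, 0.05))
  sigma_t[1, 2] <- sigma_t[2, 1] <- 0.05
  cfg <- simulation_config(n_trainees = 300, n_procedures = 8,
                           procedures_per_trainee = 4,
                           sigma_t = sigma_t, sigma_p = diag(0.02, 4),
                           sigma_tp = diag(0.2, 4), seed = 63)
  cp <- estimate_unbalanced(generate_dataset(cfg))
  expect_equal(cp$sigma_t[1, 2], 0.05, tolerance = 0.5)  # 3 MC SEs wide
  expect_lt(abs(cp$sigma_t[1, 2] - 0.05), 0.03)
})

test_that("proportion_table reproduces published-style arithmetic", {
  cp <- gstudy_components(
    sigma_t = diag(c(0.064, 0.090, 0.033, 0.097)),
    sigma_p = diag(c(0.041, 0.084, 0.013, 0.017)),
    sigma_tp = diag(c(0.317, 0.312, 0.222, 0.152)))
  expect_equal(unname(proportion_table(cp, 1)["t"]), 15.2)
  expect_equal(unname(proportion_table(cp, "score_tp")["t"]), 36.5)
  expect_equal(sum(proportion_table(cp, 2, digits = NA)), 100)

  single <- gstudy_components(diag(c(1, 1, 1, 1)), diag(0, 4), diag(0, 4))
  expect_equal(unname(proportion_table(single, 1)), c(100, 0, 0))
  zero <- gstudy_components(diag(0, 4), diag(0, 4), diag(0, 4))
  expect_error(proportion_table(zero, 1), "undefined")
})
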