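mk_rows <- function(n, pgy, complexity, trainee_offset = 0) {
  data.frame(
    trainee_id = sprintf("T%04d", trainee_offset + seq_len(n)),
    procedure_id = sprintf("P%03d", seq_len(n)),
    pgy = pgy, complexity = complexity,
    score_fa = 2, score_ta = 2, score_fp = 3, score_tp = 3)
}

test_that("stratify partitions rows by (pgy, complexity)", {
  tab <- rbind(mk_rows(3, 2, "average"), mk_rows(3, 3, "average", 10))
  st <- stratify(tab)
  expect_named(st, c("PGY2:average", "PGY3:average"))
  expect_equal(vapply(st, nrow, 0L), c("PGY2:average" = 3L,
                                       "PGY3:average" = 3L))

  single <- mk_rows(4, 5, "hardest")
  st1 <- stratify(single)
  expect_length(st1, 1L)
  expect_equal(st1[[1]], single, ignore_attr = TRUE)
})

test_that("stratum sizes match an independent tally on random labels", {
  set.seed(123)
  n <- 10000L
  tab <- data.frame(
    trainee_id = sprintf("T%05d", seq_len(n)),
    procedure_id = sprintf("P%03d", sample(200, n, TRUE)),
    pgy = sample(1:5, n, TRUE),
    complexity = sample(c("easiest", "average", "hardest"), n, TRUE),
    score_fa = 2, score_ta = 2, score_fp = 3, score_tp = 3)
  st <- stratify(tab)
  expect_equal(sum(vapply(st, nrow, 0L)), n)
  tally <- table(paste0("PGY", tab$pgy, ":", tab$complexity))
  expect_equal(vapply(st, nrow, 0L)[names(tally)], c(tally))
})

balanced_fixture <- function(n_trainees = 300, n_procedures = 12,
                             seed = 5) {
  cfg <- simulation_config(n_trainees = n_trainees,
                           n_procedures = n_procedures, seed = seed)
  generate_dataset(cfg)
}

test_that("sample_balanced applies the two filters then thins uniformly", {
  ## forced selection: a trainee with exactly k procedures keeps all of them
  tab <- data.frame(
    trainee_id = "T0001", procedure_id = sprintf("P%03d", 1:3),
    pgy = 5L, complexity = "average",
    score_fa = 2, score_ta = 2, score_fp = 3, score_tp = 3)
  out <- sample_balanced(tab, sampling_config(3, 1, seed = 1))
  expect_equal(sort(out$procedure_id), sort(tab$procedure_id))

  ## threshold boundary: 49 trainees < 50 drops the procedure
  tab49 <- data.frame(
    trainee_id = sprintf("T%04d", 1:49), procedure_id = "P001",
    pgy = 5L, complexity = "average",
    score_fa = 2, score_ta = 2, score_fp = 3, score_tp = 3)
  expect_error(sample_balanced(tab49, sampling_config(1, 50, seed = 1)),
               "min_trainees_per_procedure", class = "design_infeasible")
  ok <- sample_balanced(rbind(tab49,
                              within(tab49[1, ], trainee_id <- "T0050")),
                        sampling_config(1, 50, seed = 1))
  expect_equal(nrow(ok), 50L)
})

test_that("thinned design is balanced and verified by a brute-force recount", {
  tab <- balanced_fixture()  # 300 trainees x 12 procedures, fully crossed
  cfg <- sampling_config(procedures_per_trainee = 3,
                         min_trainees_per_procedure = 50, seed = 77)
  out <- sample_balanced(tab, cfg)

  ## independent recount of the survivors
  eligible_proc <- names(which(
    tapply(tab$trainee_id, tab$procedure_id,
           function(x) length(unique(x))) >= 50))
  kept <- tab[tab$procedure_id %in% eligible_proc, ]
  surviving <- names(which(tapply(kept$procedure_id, kept$trainee_id,
                                  length) >= 3))
  expect_equal(nrow(out), 3L * length(surviving))
  expect_true(all(table(out$trainee_id) == 3L))
  expect_true(all(table(out$procedure_id) >= 1L))

  ## no fabrication: every output row exists in the input
  key <- function(d) paste(d$trainee_id, d$procedure_id, d$score_fa)
  expect_true(all(key(out) %in% key(tab)))
})

test_that("sample_balanced is idempotent on dense designs", {
  tab <- balanced_fixture()  # expected 300*3/12 = 75 >= 50 per procedure
  cfg <- sampling_config(3, 50, seed = 9)
  once <- sample_balanced(tab, cfg)
  again <- sample_balanced(once, sampling_config(3, 50, seed = 1234))
  ord <- function(d) d[order(d$trainee_id, d$procedure_id), ]
  expect_equal(ord(again), ord(once), ignore_attr = TRUE)
})

test_that("infeasible designs raise a named design_infeasible error", {
  tab <- balanced_fixture(n_trainees = 20, n_procedures = 4)
  expect_error(sample_balanced(tab, sampling_config(3, 50, seed = 1)),
               "threshold", class = "design_infeasible")
  expect_error(
    sample_balanced(rbind(mk_rows(3, 2, "average"),
                          mk_rows(3, 3, "average", 10)),
                    sampling_config(3, 1, seed = 1)),
    "single.*stratum")
})
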