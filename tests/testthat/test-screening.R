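test_that("exact binomial tail matches brute-force summation", {
  # dense check at the study's trial counts, spot checks elsewhere
  for (n in c(1, 2, 7, 50, 199, 200, 420, 500)) {
    k <- 0:n
    brute <- vapply(k, ref_binom_tail_log, numeric(1), n = n)
    expect_equal(binomial_screen_p(k, n), brute, tolerance = 1e-12)
  }
})

test_that("screening applies the one-tailed exact test over all trials", {
  mk <- function(id, n, k) {
    tibble::tibble(participant_id = id, age_group = "adult",
                   condition = "control", block = 1L, trial = seq_len(n),
                   soa_ms = 60, oddball_present = FALSE,
                   correct = c(rep(TRUE, k), rep(FALSE, n - k)))
  }
  # exactly at chance over 420 trials: p slightly above 0.5, excluded
  res <- exclude_at_chance(mk("at_chance", 420, 210))
  expect_equal(res$one_tailed_p, ref_binom_tail_log(210, 420))
  expect_gt(res$one_tailed_p, 0.5)
  expect_false(res$included)

  # perfect performance: p = 2^-420
  res <- exclude_at_chance(mk("perfect", 420, 420))
  expect_equal(res$one_tailed_p, 2^-420)
  expect_true(res$included)

  # minimal k for inclusion at n = 420 from the brute-force oracle
  ps <- vapply(0:420, ref_binom_tail_log, numeric(1), n = 420)
  k_min <- min(which(ps < 0.05)) - 1L
  res <- exclude_at_chance(dplyr::bind_rows(mk("just_in", 420, k_min),
                                            mk("just_out", 420, k_min - 1L)))
  expect_equal(res$included, c(TRUE, FALSE))

  # inclusion is monotone in k at fixed n
  many <- dplyr::bind_rows(lapply(180:260, function(k) {
    mk(sprintf("p%03d", k), 420, k)
  }))
  res <- exclude_at_chance(many)
  res <- res[order(res$n_correct), ]
  expect_true(all(diff(res$included) >= 0))
  expect_true(all(diff(res$one_tailed_p) <= 0))
})

test_that("pure-chance responders are included at about the alpha rate", {
  # quick calibration (the full 10,000-participant version runs in the
  # acceptance suite); trial-level simulation through the generator
  sim <- simulate_experiment(
    design_spec(n_per_cell = 100, n_blocks = 2, trials_per_block = 210,
                seed = 13),
    ground_truth(fraction_at_chance = 0.999999)
  )
  res <- exclude_at_chance(sim$trials)
  rate <- mean(res$included)
  # the discrete test is conservative: rate <= 0.05, close for n = 420
  expect_lt(rate, 0.08)
  expect_gt(rate, 0.01)
})

test_that("truncation keeps the first trials and preserves indices", {
  sim <- tiny_sim(seed = 14, n_per_cell = 1, trials = 210)
  tr <- truncate_trials(sim$trials, 200)
  expect_true(all(tr$trial <= 200))
  per <- dplyr::count(tr, participant_id)
  expect_true(all(per$n == 200))
  expect_identical(truncate_trials(sim$trials, 420), sim$trials)
  expect_identical(truncate_trials(sim$trials, Inf), sim$trials)
  one <- truncate_trials(sim$trials, 1)
  expect_equal(nrow(one), nrow(sim$participants))
  expect_error(truncate_trials(sim$trials, 0))
})

test_that("the inclusion table is cells-by-condition shaped", {
  sim <- simulate_experiment(
    design_spec(n_per_cell = 4, n_blocks = 1, trials_per_block = 100,
                seed = 15),
    ground_truth(a_intercept = log(0.01), s_intercept = log(0.01),
                 fraction_at_chance = 0)
  )
  res <- exclude_at_chance(sim$trials)
  expect_true(all(res$included))  # everyone far above chance
  tab <- screening_summary(res, sim$trials)
  expect_equal(nrow(tab), 2)
  expect_setequal(setdiff(names(tab), "age_group"),
                  c("control", "positive", "stress"))
  expect_true(all(as.matrix(tab[, -1]) == 4))
})
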