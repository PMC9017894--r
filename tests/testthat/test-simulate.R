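test_that("simulated experiments have the exact design shape", {
  sim <- tiny_sim(seed = 1, n_per_cell = 3, trials = 20)
  expect_equal(nrow(sim$participants), 2 * 3 * 3)
  expect_equal(nrow(sim$trials), 18 * 2 * 20)
  per <- dplyr::count(sim$trials, participant_id)
  expect_true(all(per$n == 40))
  idx <- sim$trials |>
    dplyr::group_by(participant_id) |>
    dplyr::summarise(ok = identical(sort(trial), 1:40))
  expect_true(all(idx$ok))
  expect_true(all(sim$trials$soa_ms %in% c(15, 30, 60, 90, 120, 300, 500)))
  expect_true(all(sim$trials$block == ifelse(sim$trials$trial <= 20, 1, 2)))
})

test_that("same seed reproduces the simulation exactly", {
  s1 <- tiny_sim(seed = 9)
  s2 <- tiny_sim(seed = 9)
  expect_identical(s1$trials, s2$trials)
  expect_identical(s1$participants, s2$participants)
  s3 <- tiny_sim(seed = 10)
  expect_false(identical(s1$trials$correct, s3$trials$correct))
})

test_that("accuracy floors at chance when thresholds dwarf every SOA", {
  sim <- simulate_experiment(
    design_spec(n_per_cell = 5, n_blocks = 2, trials_per_block = 200,
                seed = 3),
    ground_truth(a_intercept = log(10), s_intercept = log(10),
                 a_age = 0, s_age = 0, sigma_a = 0, sigma_s = 0,
                 lapse = 0, fraction_at_chance = 0)
  )
  acc <- mean(sim$trials$correct)
  se <- sqrt(0.25 / nrow(sim$trials))
  expect_lt(abs(acc - 0.5), 3 * se)
})

test_that("accuracy saturates near the lapse ceiling for tiny thresholds", {
  sim <- simulate_experiment(
    design_spec(n_per_cell = 5, n_blocks = 2, trials_per_block = 200,
                seed = 4),
    ground_truth(a_intercept = log(1e-4), s_intercept = log(1e-4),
                 a_age = 0, s_age = 0, sigma_a = 0, sigma_s = 0,
                 lapse = 0.01, fraction_at_chance = 0)
  )
  acc <- mean(sim$trials$correct)
  se <- sqrt(0.01 * 0.99 / nrow(sim$trials))
  expect_gt(acc, 1 - 0.01 - 3 * se)
})

test_that("empirical accuracy per SOA converges to the psychometric function", {
  # freeze the trajectory (S = A) so all trials share one threshold
  th <- 0.09; beta <- 3; eps <- 0.01
  sim <- simulate_experiment(
    design_spec(n_per_cell = 12, n_blocks = 2, trials_per_block = 150,
                seed = 5),
    ground_truth(a_intercept = log(th), s_intercept = log(th),
                 a_age = 0, s_age = 0, sigma_a = 0, sigma_s = 0,
                 sigma_shape = 0, log_shape = log(beta), lapse = eps,
                 fraction_at_chance = 0)
  )
  by_soa <- sim$trials |>
    dplyr::group_by(soa_ms) |>
    dplyr::summarise(acc = mean(correct), n = dplyr::n())
  p_true <- pf_probability(by_soa$soa_ms / 1000, th, beta, eps)
  se <- sqrt(p_true * (1 - p_true) / by_soa$n)
  expect_true(all(abs(by_soa$acc - p_true) < 4 * se))
})

test_that("an injected asymptote difference shows up in late-trial accuracy", {
  sim <- simulate_experiment(
    design_spec(n_per_cell = 30, n_blocks = 2, trials_per_block = 100,
                seed = 6),
    ground_truth(a_arousal = 1.2, sigma_a = 0.2, fraction_at_chance = 0)
  )
  late <- sim$trials |>
    dplyr::filter(trial > 150) |>
    dplyr::group_by(arousal = condition != "control") |>
    dplyr::summarise(acc = mean(correct))
  # positive arousal coefficient raises the asymptotic threshold -> worse
  expect_lt(late$acc[late$arousal], late$acc[!late$arousal])
})

test_that("at-chance participants are flagged and respond at chance", {
  sim <- simulate_experiment(
    design_spec(n_per_cell = 6, n_blocks = 1, trials_per_block = 300,
                seed = 7),
    ground_truth(fraction_at_chance = 0.5,
                 a_intercept = log(0.01), s_intercept = log(0.01))
  )
  flagged <- sim$participants$participant_id[sim$participants$at_chance]
  expect_gt(length(flagged), 0)
  acc <- sim$trials |>
    dplyr::filter(participant_id %in% flagged) |>
    dplyr::summarise(acc = mean(correct), n = dplyr::n())
  expect_lt(abs(acc$acc - 0.5), 4 * sqrt(0.25 / acc$n))
})

test_that("balanced SOA assignment balances levels within blocks", {
  d <- design_spec(n_per_cell = 1, n_blocks = 2, trials_per_block = 70,
                   balanced_soa = TRUE, seed = 8)
  sim <- simulate_experiment(d, ground_truth(fraction_at_chance = 0))
  counts <- sim$trials |>
    dplyr::count(participant_id, block, soa_ms)
  expect_true(all(counts$n == 10))
})

test_that("moving-proportion smoother matches brute-force enumeration", {
  # constant accuracy stays constant under any window
  const <- tibble::tibble(
    participant_id = "p1", age_group = "adult", condition = "control",
    block = 1L, trial = 1:50, soa_ms = 60,
    oddball_present = FALSE, correct = TRUE
  )
  sm <- smooth_accuracy(const, window = 9)
  expect_true(all(sm$accuracy == 1))

  # window 1 is the identity on per-trial proportions
  set.seed(11)
  rnd <- const
  rnd$correct <- runif(50) < 0.7
  sm1 <- smooth_accuracy(rnd, window = 1)
  expect_equal(sm1$accuracy, as.numeric(rnd$correct))

  # alternating sequence, window 2, vs direct enumeration of the same
  # truncated centered-window definition
  alt <- const
  alt$correct <- rep(c(FALSE, TRUE), 25)
  sm2 <- smooth_accuracy(alt, window = 2)
  brute <- sapply(1:50, function(t) {
    win <- intersect(t:(t + 1), 1:50)
    mean(alt$correct[win])
  })
  expect_equal(sm2$accuracy, brute)
  expect_true(all(sm2$accuracy[1:49] == 0.5))
  expect_equal(sm2$accuracy[50], 1)

  expect_warning(out <- smooth_accuracy(const[0, ], 5), "no trials")
  expect_equal(nrow(out), 0)
})

test_that("simulations round-trip through the CSV writer", {
  sim <- tiny_sim(seed = 12, n_per_cell = 1, trials = 5)
  dir <- withr::local_tempdir()
  man <- write_simulation(sim, dir)
  expect_true(file.exists(file.path(dir, "trials.csv")))
  expect_true(file.exists(file.path(dir, "simulation_manifest.json")))
  back <- utils::read.csv(file.path(dir, "trials.csv"))
  expect_equal(nrow(back), nrow(sim$trials))
  expect_equal(back$correct, sim$trials$correct)
})
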