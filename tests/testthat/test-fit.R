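test_that("sampling is deterministic given the seed", {
  sim <- tiny_sim(seed = 30, n_per_cell = 1, trials = 15)
  mc <- mcmc_control(chains = 2, warmup = 80, iter = 60)
  f1 <- suppressWarnings(fit_learning_model(sim$trials, model_spec("null"),
                                            mc, seed = 3))
  f2 <- suppressWarnings(fit_learning_model(sim$trials, model_spec("null"),
                                            mc, seed = 3))
  expect_identical(f1$draws, f2$draws)
  f3 <- suppressWarnings(fit_learning_model(sim$trials, model_spec("null"),
                                            mc, seed = 4))
  expect_false(identical(f1$draws, f3$draws))
})

test_that("a small fit recovers the flat-threshold truth region", {
  # no learning, tight truth: posterior for the asymptote intercept should
  # land near log(0.08) with high probability
  sim <- simulate_experiment(
    design_spec(n_per_cell = 2, n_blocks = 2, trials_per_block = 120,
                seed = 31),
    ground_truth(a_intercept = log(0.08), s_intercept = log(0.08),
                 a_age = 0, s_age = 0, sigma_a = 0.1, sigma_s = 0.1,
                 sigma_r = 0.1, sigma_shape = 0.1, fraction_at_chance = 0)
  )
  fit <- suppressWarnings(fit_learning_model(
    sim$trials, model_spec("null"),
    mcmc_control(chains = 2, warmup = 250, iter = 250), seed = 8))
  td <- tidy(fit)
  asym <- td[td$term == "Asym: Intercept", ]
  expect_lt(asym$conf.low, log(0.08))
  expect_gt(asym$conf.high, log(0.08) + 0.0)
  expect_lt(abs(asym$estimate - log(0.08)), 0.5)
})

test_that("the fit carries coherent draws, diagnostics and metadata", {
  fit <- cached_tiny_fit()
  expect_s3_class(fit, "pl_fit")
  expect_equal(nrow(fit$draws), 2 * 150)
  expect_equal(ncol(fit$draws), length(fit$par_names))
  expect_equal(length(fit$chain), nrow(fit$draws))
  expect_equal(nrow(fit$diagnostics), length(fit$par_names))
  expect_true(all(is.finite(fit$diagnostics$rhat)))
  expect_true(all(fit$diagnostics$ess_bulk > 0))
  g <- glance(fit)
  expect_equal(g$draws, 300)
  expect_equal(g$n_participants, 12)
  expect_output(print(fit), "pl_fit")
})

test_that("full-model coefficient tables mirror the 19-row layout", {
  sim <- tiny_sim(seed = 33, n_per_cell = 1, trials = 10)
  lik <- build_likelihood(sim$trials, model_spec("full"))
  terms <- perceptlearn:::order_fixed_terms(lik$prep$fixed_terms)
  comp <- c("Asym", "Start", "Rate")
  within <- c("Intercept", "age", "arousal", "age × arousal", "valence",
              "age × valence")
  expect_equal(terms,
               c(as.vector(t(outer(comp, within, paste, sep = ": "))),
                 "PF shape: Intercept"))
  expect_length(terms, 19)

  # per-age effect models carry the 7-row layout
  lik_v <- build_likelihood(dplyr::filter(sim$trials, age_group == "adult"),
                            model_spec("valence", age = "adult"))
  expect_equal(perceptlearn:::order_fixed_terms(lik_v$prep$fixed_terms),
               c("Asym: Intercept", "Asym: valence", "Start: Intercept",
                 "Start: valence", "Rate: Intercept", "Rate: valence",
                 "PF shape: Intercept"))
})

test_that("reliability flags follow the credible interval exactly", {
  fit <- cached_tiny_fit()
  fake <- fit
  fake$draws[, "Asym: arousal"] <- 0.5        # point mass away from zero
  set.seed(1)
  fake$draws[, "Start: arousal"] <- rnorm(nrow(fake$draws))  # straddles 0
  td <- summarize_fixed_effects(fake)
  arow <- td[td$term == "Asym: arousal", ]
  expect_equal(arow$estimate, 0.5)
  expect_equal(c(arow$conf.low, arow$conf.high), c(0.5, 0.5))
  expect_true(arow$reliable)
  expect_false(td$reliable[td$term == "Start: arousal"])
})

test_that("monotonic valence contributions never cross within a draw", {
  fit <- cached_tiny_fit()  # full model without interactions, mono on
  dat <- fit$prep$data
  idx <- perceptlearn:::par_layout(dat)
  for (c_i in 1:3) {
    bv <- fit$draws[, idx$bv[c_i]]
    z1 <- stats::plogis(fit$draws[, idx$r[c_i]])
    contrib <- cbind(stress = 0, control = bv * z1, positive = bv)
    ordered_up <- contrib[, 1] <= contrib[, 2] & contrib[, 2] <= contrib[, 3]
    ordered_dn <- contrib[, 1] >= contrib[, 2] & contrib[, 2] >= contrib[, 3]
    expect_true(all(ordered_up | ordered_dn))
  }
})

test_that("posterior learning magnitudes collapse to zero when S = A", {
  fit <- cached_tiny_fit()
  frozen <- fit
  dat <- fit$prep$data
  idx <- perceptlearn:::par_layout(dat)
  # force S components identical to A components, draw by draw
  frozen$draws[, idx$bS] <- frozen$draws[, idx$bA]
  if (dat$has_mono) {
    frozen$draws[, idx$bv[2]] <- frozen$draws[, idx$bv[1]]
    frozen$draws[, idx$r[2]] <- frozen$draws[, idx$r[1]]
  }
  frozen$draws[, idx$zS] <- frozen$draws[, idx$zA] *
    exp(frozen$draws[, idx$logsig[1]] - frozen$draws[, idx$logsig[2]])
  mag <- posterior_learning_magnitude(frozen)
  expect_true(all(abs(mag$participants$estimate) < 1e-12))
  expect_true(all(abs(mag$contrasts$estimate) < 1e-12))
})

test_that("posterior magnitudes match the closed form for frozen draws", {
  fit <- cached_tiny_fit()
  frozen <- fit
  frozen$draws[] <- 0   # every component pinned at its coded zero
  dat <- fit$prep$data
  idx <- perceptlearn:::par_layout(dat)
  frozen$draws[, idx$bA] <- 0
  frozen$draws[, idx$bA[1]] <- -2.6
  frozen$draws[, idx$bS[1]] <- 0.2
  frozen$draws[, idx$bR[1]] <- 1.5
  frozen$draws[, idx$bsh] <- 1.1
  frozen$draws[, idx$logsig] <- -30  # random effects effectively zero
  mag <- posterior_learning_magnitude(frozen)
  mean_soa <- mean(fit$prep$records$soa_ms) / 1000
  t_end <- max(fit$prep$records$trial)
  expected <- learning_magnitude(0.2, -2.6, 1.5, exp(1.1),
                                 lapse = dat$lapse, mean_soa_s = mean_soa,
                                 t_start = 1, t_end = t_end)
  expect_equal(unique(round(mag$participants$estimate, 10)),
               round(expected, 10))
  expect_true(all(abs(mag$contrasts$estimate) < 1e-12))
})
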