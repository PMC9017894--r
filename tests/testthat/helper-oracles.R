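# Independent reference implementations used as oracles. These are written
# directly from the model definitions and deliberately avoid the package's
# own code paths.

# reference Quick PF with guessing floor and lapse
ref_pf <- function(soa, th, beta, eps) {
  0.5 + (0.5 - eps) * (1 - 2^(-(soa / th)^beta))
}

# reference threshold trajectory
ref_threshold <- function(t, S, A, R) {
  exp(A + (S - A) * 2^(-(t - 1) / 10^R))
}

# brute-force per-trial Bernoulli log likelihood for given participant-level
# parameter values (plain R loop; no shared code with the compiled density)
ref_loglik <- function(records, pars, lapse) {
  ll <- 0
  for (i in seq_len(nrow(records))) {
    row <- records[i, ]
    pp <- pars[pars$participant_id == row$participant_id, ]
    th <- ref_threshold(row$trial, pp$S, pp$A, pp$R)
    p <- ref_pf(row$soa_ms / 1000, th, pp$beta, lapse)
    ll <- ll + if (row$correct) log(p) else log(1 - p)
  }
  ll
}

# brute-force one-tailed binomial tail probability
ref_binom_tail <- function(k, n) {
  if (k > n) return(0)
  sum(choose(n, k:n)) * 2^(-n)  # valid for moderate n; see large-n variant
}

# numerically safe variant for all n <= 500
ref_binom_tail_log <- function(k, n) {
  if (k > n) return(0)
  j <- k:n
  sum(exp(lchoose(n, j) - n * log(2)))
}

# small deterministic simulated data set shared across tests
tiny_sim <- function(seed = 42, n_per_cell = 2, trials = 30, ...) {
  simulate_experiment(
    design_spec(n_per_cell = n_per_cell, n_blocks = 2,
                trials_per_block = trials, seed = seed),
    ground_truth(fraction_at_chance = 0, ...)
  )
}

# a very small but real fit, cached per session for reuse across tests
cached_tiny_fit <- local({
  cache <- new.env(parent = emptyenv())
  function() {
    if (is.null(cache$fit)) {
      sim <- tiny_sim(seed = 7, n_per_cell = 2, trials = 25)
      cache$fit <- suppressWarnings(fit_learning_model(
        sim$trials, model_spec("full", include_interactions = FALSE),
        mcmc_control(chains = 2, warmup = 150, iter = 150), seed = 5
      ))
    }
    cache$fit
  }
})
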