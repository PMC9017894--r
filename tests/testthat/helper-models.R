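# Shared builders for likelihood-oracle instances and conjugate toy
# models with closed-form marginal likelihoods.

# helpers to build a parameter vector realizing chosen participant-level
# component values in the null model (K = 1, non-centered random effects)
null_par_for <- function(lik, pars) {
  dat <- lik$prep$data
  idx <- perceptlearn:::par_layout(dat)
  ord <- match(lik$prep$participants$participant_id, pars$participant_id)
  pars <- pars[ord, ]
  par <- numeric(lik$n_par)
  par[idx$logsig] <- 0  # sigma = 1 so z equals the centered offset
  par[idx$bA] <- 0; par[idx$bS] <- 0; par[idx$bR] <- 0
  par[idx$bsh] <- 0
  par[idx$zA] <- pars$A
  par[idx$zS] <- pars$S
  par[idx$zR] <- pars$R
  par[idx$zsh] <- log(pars$beta)
  par
}

random_instance <- function(seed) {
  set.seed(seed)
  n_p <- sample(1:3, 1)
  n_t <- sample(10:50, 1)
  pars <- tibble::tibble(
    participant_id = paste0("p", seq_len(n_p)),
    A = runif(n_p, -3.5, -1.5),
    S = runif(n_p, -1.5, 1),
    R = runif(n_p, 0.5, 2),
    beta = exp(runif(n_p, 0.5, 1.6))
  )
  records <- purrr::map_dfr(pars$participant_id, function(id) {
    tibble::tibble(
      participant_id = id, age_group = "adult", condition = "control",
      block = 1L, trial = seq_len(n_t),
      soa_ms = sample(c(15, 30, 60, 90, 120, 300, 500), n_t, TRUE),
      oddball_present = FALSE,
      correct = runif(n_t) < 0.75
    )
  })
  list(pars = pars, records = records, lapse = runif(1, 0, 0.1))
}

# conjugate toy models with closed-form marginal likelihoods
normal_normal_toy <- function(seed = 1, n = 30, s2 = 4, m0 = 1, t2 = 2.25,
                              n_draws = 2000) {
  set.seed(seed)
  y <- rnorm(n, 2, sqrt(s2))
  Sig <- diag(s2, n) + t2
  lml <- as.numeric(-0.5 * (n * log(2 * pi) +
                              determinant(Sig)$modulus +
                              t(y - m0) %*% solve(Sig) %*% (y - m0)))
  post_var <- 1 / (n / s2 + 1 / t2)
  post_mean <- post_var * (sum(y) / s2 + m0 / t2)
  draws <- matrix(rnorm(n_draws, post_mean, sqrt(post_var)), ncol = 1)
  log_post <- function(par) {
    sum(dnorm(y, par[1], sqrt(s2), log = TRUE)) +
      dnorm(par[1], m0, sqrt(t2), log = TRUE)
  }
  list(lml = lml, draws = draws, log_post = log_post)
}

beta_bernoulli_toy <- function(seed = 1, n = 40, k = 27, a = 2, b = 3,
                               n_draws = 2000) {
  set.seed(seed)
  lml <- lbeta(a + k, b + n - k) - lbeta(a, b)
  draws <- matrix(qlogis(rbeta(n_draws, a + k, b + n - k)), ncol = 1)
  log_post <- function(par) {
    th <- plogis(par[1])
    k * log(th) + (n - k) * log(1 - th) +
      dbeta(th, a, b, log = TRUE) + log(th * (1 - th))  # logit Jacobian
  }
  list(lml = lml, draws = draws, log_post = log_post)
}
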