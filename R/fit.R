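#' Construct the model log density as an R function
#'
#' Compiles the screened, truncated records and a [model_spec()] into a
#' log-density closure over the unconstrained parameter vector. The closure
#' evaluates the trial-level Bernoulli likelihood through the time-evolving
#' psychometric function and, by default, adds the log prior (with the
#' Jacobians of the internal transforms), so it is the target the sampler
#' and the bridge estimator share.
#'
#' @param records A trials data frame (screened and truncated).
#' @param spec A [model_spec()].
#' @return A `pl_likelihood` list with elements `log_density(par,
#'   include_prior = TRUE)`, `grad(par, include_prior = TRUE)`, `n_par`,
#'   `par_names` and the prepared internals.
#' @export
build_likelihood <- function(records, spec = model_spec("full")) {
  prep <- prepare_model_data(records, spec)
  dat <- prep$data
  structure(
    list(
      log_density = function(par, include_prior = TRUE) {
        pl_lp(par, dat, include_prior)
      },
      grad = function(par, include_prior = TRUE) {
        pl_lp_grad(par, dat, include_prior)$grad
      },
      n_par = pl_n_par(dat),
      par_names = prep$par_names,
      spec = spec,
      prep = prep
    ),
    class = "pl_likelihood"
  )
}

# Draw an initial unconstrained parameter vector near the prior centers.
draw_init <- function(prep, spec) {
  dat <- prep$data
  K <- ncol(dat$X)
  P <- dat$P
  pr <- spec$priors
  b0 <- function(cmp_mean) {
    c(cmp_mean + 0.1 * stats::rnorm(1), 0.1 * stats::rnorm(K - 1))
  }
  init <- c(b0(pr$a_intercept[1]), b0(pr$s_intercept[1]),
            b0(pr$r_intercept[1]))
  if (dat$has_mono) init <- c(init, 0.1 * stats::rnorm(3))
  if (dat$mono_int) init <- c(init, 0.1 * stats::rnorm(3))
  if (dat$has_mono) init <- c(init, 0.2 * stats::rnorm(3))
  init <- c(init, pr$shape[1] + 0.1 * stats::rnorm(1))
  init <- c(init, log(0.3) + 0.2 * stats::rnorm(4))
  init <- c(init, 0.1 * stats::rnorm(4 * P))
  if (dat$est_lapse) init <- c(init, stats::qlogis(2 * 0.01))
  init
}

#' Fit the hierarchical learning model by Hamiltonian Monte Carlo
#'
#' Samples the posterior of the trial-level learning model with an adaptive
#' HMC sampler (dual-averaging step size, diagonal mass matrix learned
#' during warmup, non-centered random effects). Chains run serially with
#' seeds derived from `seed`; two calls with identical data, spec and seed
#' produce identical draws.
#'
#' @param records A trials data frame, already screened with
#'   [exclude_at_chance()] and truncated with [truncate_trials()].
#' @param spec A [model_spec()].
#' @param mcmc An [mcmc_control()].
#' @param seed Integer seed for all sampling randomness.
#' @param quiet Suppress per-chain progress messages.
#' @return A `pl_fit` object: draw matrix (`chains * iter` rows, one column
#'   per unconstrained parameter), parameter names, per-parameter
#'   convergence diagnostics (split R-hat, bulk ESS), divergence counts,
#'   and the prepared data needed by downstream summaries. A warning (not
#'   an error) is raised when max split R-hat exceeds 1.01 or any
#'   divergences occurred.
#' @export
fit_learning_model <- function(records, spec = model_spec("full"),
                               mcmc = mcmc_control(), seed = 1,
                               quiet = TRUE) {
  stopifnot(inherits(spec, "pl_model_spec"), inherits(mcmc, "pl_mcmc"))
  prep <- prepare_model_data(records, spec)
  dat <- prep$data
  D <- pl_n_par(dat)

  chains <- vector("list", mcmc$chains)
  divergences <- integer(mcmc$chains)
  step_sizes <- accept <- numeric(mcmc$chains)
  t0 <- Sys.time()
  for (ch in seq_len(mcmc$chains)) {
    set.seed(seed + 1000L * (ch - 1L))
    init <- NULL
    for (try in 1:100) {
      cand <- draw_init(prep, spec)
      if (is.finite(pl_lp(cand, dat, TRUE))) { init <- cand; break }
    }
    if (is.null(init)) {
      stop("could not find a finite initial density after 100 draws.",
           call. = FALSE)
    }
    res <- pl_hmc(dat, init, mcmc$warmup, mcmc$iter,
                  init_step = mcmc$init_step,
                  target_accept = mcmc$target_accept,
                  max_leapfrog = mcmc$max_leapfrog)
    chains[[ch]] <- res
    divergences[ch] <- res$divergences
    step_sizes[ch] <- res$step_size
    accept[ch] <- res$accept_rate
    if (!quiet) {
      message(sprintf("chain %d: accept %.2f, step %.3g, %d divergence(s)",
                      ch, res$accept_rate, res$step_size, res$divergences))
    }
  }

  draws <- do.call(rbind, lapply(chains, `[[`, "draws"))
  colnames(draws) <- prep$par_names
  lp <- unlist(lapply(chains, `[[`, "lp"))
  chain_id <- rep(seq_len(mcmc$chains), each = mcmc$iter)

  diag_tbl <- convergence_diagnostics(draws, chain_id, prep$par_names)

  fit <- structure(
    list(draws = draws, lp = lp, chain = chain_id,
         par_names = prep$par_names, fixed_terms = prep$fixed_terms,
         spec = spec, mcmc = mcmc, seed = seed, prep = prep,
         diagnostics = diag_tbl, divergences = sum(divergences),
         accept_rate = mean(accept), step_size = step_sizes,
         elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
    class = "pl_fit"
  )

  max_rhat <- max(diag_tbl$rhat, na.rm = TRUE)
  if (is.finite(max_rhat) && max_rhat > 1.01) {
    warning(sprintf("max split R-hat = %.3f > 1.01; inspect convergence.",
                    max_rhat), call. = FALSE)
  }
  if (fit$divergences > 0) {
    warning(sprintf("%d divergent transition(s) after warmup.",
                    fit$divergences), call. = FALSE)
  }
  fit
}

#' @export
print.pl_fit <- function(x, ...) {
  cat("<pl_fit> model '", x$spec$model, "' (age: ", x$spec$age, ")\n",
      sep = "")
  cat("  ", nrow(x$prep$participants), " participants, ",
      nrow(x$prep$records), " trials, ", length(x$par_names),
      " parameters\n", sep = "")
  cat("  ", max(x$chain), " chain(s) x ", sum(x$chain == 1L),
      " draws; mean accept ", sprintf("%.2f", x$accept_rate),
      "; divergences ", x$divergences, "\n", sep = "")
  cat("  max split R-hat ", sprintf("%.3f", max(x$diagnostics$rhat)),
      ", min bulk ESS ", sprintf("%.0f", min(x$diagnostics$ess_bulk)),
      "\n", sep = "")
  invisible(x)
}
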