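# Meng-Wong iterative bridge estimator of the log marginal likelihood with
# a moment-matched multivariate-normal proposal in the unconstrained space.

dmvnorm_log <- function(x, mean, chol_cov) {
  # x: matrix (rows = points); chol_cov: upper-triangular Cholesky factor
  d <- length(mean)
  z <- backsolve(chol_cov, t(x) - mean, transpose = TRUE)
  -0.5 * colSums(z^2) - sum(log(diag(chol_cov))) - 0.5 * d * log(2 * pi)
}

rmvnorm_chol <- function(n, mean, chol_cov) {
  d <- length(mean)
  z <- matrix(stats::rnorm(n * d), n, d)
  sweep(z %*% chol_cov, 2, mean, `+`)
}

# robust Cholesky: progressively ridge the covariance if needed
chol_ridged <- function(S) {
  scale <- mean(diag(S))
  for (ridge in c(0, 1e-8, 1e-6, 1e-4, 1e-2) * scale) {
    ch <- tryCatch(chol(S + ridge * diag(nrow(S))), error = function(e) NULL)
    if (!is.null(ch)) return(ch)
  }
  stop("draw covariance is rank deficient; use more posterior draws.",
       call. = FALSE)
}

# core iteration on log ratios; returns log r
bridge_iterate <- function(l_post, l_prop, tol = 1e-8, max_iter = 1000) {
  n1 <- length(l_post)  # posterior evaluation draws
  n2 <- length(l_prop)  # proposal draws
  s1 <- n1 / (n1 + n2)
  s2 <- n2 / (n1 + n2)
  lstar <- stats::median(l_post)
  e1 <- exp(l_post - lstar)
  e2 <- exp(l_prop - lstar)
  r <- 1
  for (i in seq_len(max_iter)) {
    num <- mean(e2 / (s1 * e2 + s2 * r))
    den <- mean(1 / (s1 * e1 + s2 * r))
    r_new <- num / den
    if (!is.finite(r_new) || r_new <= 0) {
      stop("bridge iteration diverged (non-finite ratio).", call. = FALSE)
    }
    if (abs(r_new - r) / r_new < tol) {
      return(list(log_r = log(r_new) + lstar, iterations = i,
                  converged = TRUE))
    }
    r <- r_new
  }
  warning("bridge iteration did not converge within ", max_iter,
          " iterations.", call. = FALSE)
  list(log_r = log(r) + lstar, iterations = max_iter, converged = FALSE)
}

#' Bridge-sampling estimate of a log marginal likelihood
#'
#' Given posterior draws in an unconstrained space and the corresponding
#' unnormalized log-posterior function (log likelihood + log prior + any
#' transform Jacobians), estimates the log marginal likelihood by the
#' iterative Meng-Wong bridge identity. The proposal is a multivariate
#' normal moment-matched to one random half of the draws; the estimator is
#' evaluated on the other half. The Monte Carlo error is estimated by
#' recomputing the estimator on paired blocks of the evaluation draws.
#'
#' @param draws Matrix of posterior draws (rows = draws, columns =
#'   unconstrained parameters).
#' @param log_post Function taking one parameter vector and returning the
#'   unnormalized log posterior density.
#' @param seed Integer seed controlling the half-split and proposal draws.
#' @param tol Relative-change convergence tolerance of the iteration.
#' @param max_iter Maximum bridge iterations.
#' @param n_blocks Blocks for the Monte Carlo error estimate.
#' @return A list of class `pl_bridge` with `log_ml`, `mc_error`,
#'   `iterations`, `converged`.
#' @export
bridge_sampler <- function(draws, log_post, seed = 1, tol = 1e-8,
                           max_iter = 1000, n_blocks = 5) {
  stopifnot(is.matrix(draws), nrow(draws) >= 20)
  set.seed(seed)
  n <- nrow(draws)
  idx <- sample.int(n)
  half1 <- draws[idx[seq_len(n %/% 2)], , drop = FALSE]        # moments
  half2 <- draws[idx[(n %/% 2 + 1):n], , drop = FALSE]          # evaluation

  mu <- colMeans(half1)
  S <- stats::cov(half1)
  # light shrinkage toward the diagonal when draws are scarce relative to
  # the dimension; heavy shrinkage would erase posterior correlations and
  # destroy proposal overlap
  d <- ncol(draws)
  lambda <- min(0.5, d / (4 * nrow(half1)))
  if (lambda > 0) S <- (1 - lambda) * S + lambda * diag(diag(S), d)
  ch <- chol_ridged(S)

  n1 <- nrow(half2)
  prop <- rmvnorm_chol(n1, mu, ch)

  lp_eval <- apply(half2, 1, log_post)
  lp_prop <- apply(prop, 1, log_post)
  lq_eval <- dmvnorm_log(half2, mu, ch)
  lq_prop <- dmvnorm_log(prop, mu, ch)
  lp_prop[!is.finite(lp_prop)] <- -Inf  # proposal mass outside support

  res <- bridge_iterate(lp_eval - lq_eval, lp_prop - lq_prop,
                        tol = tol, max_iter = max_iter)

  blocks <- cut(seq_len(n1), n_blocks, labels = FALSE)
  block_est <- vapply(seq_len(n_blocks), function(b) {
    keep <- blocks == b
    bridge_iterate((lp_eval - lq_eval)[keep], (lp_prop - lq_prop)[keep],
                   tol = tol, max_iter = max_iter)$log_r
  }, numeric(1))
  mc_error <- stats::sd(block_est) / sqrt(n_blocks)

  structure(list(log_ml = res$log_r, mc_error = mc_error,
                 iterations = res$iterations, converged = res$converged,
                 n_draws = n), class = "pl_bridge")
}

#' Log marginal likelihood of a fitted learning model
#'
#' Applies [bridge_sampler()] to the fit's posterior draws and its own
#' unnormalized log posterior (likelihood + priors + transform Jacobians in
#' the unconstrained space). Requires at least two chains and a minimum
#' effective sample size so the moment-matched proposal is trustworthy.
#'
#' @param fit A `pl_fit`.
#' @param seed Seed for the split and proposal randomness.
#' @param min_ess Minimum bulk ESS required across parameters (warning
#'   below).
#' @param ... Passed to [bridge_sampler()].
#' @return A `pl_bridge` list.
#' @export
log_marginal_likelihood <- function(fit, seed = 1, min_ess = 400, ...) {
  stopifnot(inherits(fit, "pl_fit"))
  if (max(fit$chain) < 2) {
    stop("bridge sampling requires at least 2 chains.", call. = FALSE)
  }
  ess <- min(fit$diagnostics$ess_bulk, na.rm = TRUE)
  if (is.finite(ess) && ess < min_ess) {
    warning(sprintf(
      "min bulk ESS %.0f < %d; bridge estimate may be unstable.",
      ess, min_ess), call. = FALSE)
  }
  dat <- fit$prep$data
  bridge_sampler(fit$draws, function(par) pl_lp(par, dat, TRUE),
                 seed = seed, ...)
}

#' @export
print.pl_bridge <- function(x, ...) {
  cat(sprintf("<pl_bridge> log ML = %.3f (MC error %.3g, %d iterations%s)\n",
              x$log_ml, x$mc_error, x$iterations,
              if (x$converged) "" else ", NOT converged"))
  invisible(x)
}
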