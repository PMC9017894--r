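# Convergence diagnostics: split R-hat and a Geyer-pairs bulk ESS computed
# on split chains. Self-contained implementations of the standard formulas.

split_chain_matrix <- function(x, chain_id) {
  # returns an (n/2) x (2 * n_chains) matrix of split half-chains
  chains <- split(x, chain_id)
  halves <- unlist(lapply(chains, function(v) {
    n <- length(v)
    h <- n %/% 2
    list(v[seq_len(h)], v[(n - h + 1):n])
  }), recursive = FALSE)
  n <- min(lengths(halves))
  vapply(halves, function(v) v[seq_len(n)], numeric(n))
}

split_rhat <- function(x, chain_id) {
  m <- split_chain_matrix(x, chain_id)
  n <- nrow(m)
  if (n < 3) return(NA_real_)
  means <- colMeans(m)
  vars <- apply(m, 2, stats::var)
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W == 0) return(if (B == 0) 1 else Inf)
  sqrt(((n - 1) / n * W + B / n) / W)
}

ess_bulk <- function(x, chain_id) {
  m <- split_chain_matrix(x, chain_id)
  n <- nrow(m)
  k <- ncol(m)
  if (n < 3) return(NA_real_)
  vars <- apply(m, 2, stats::var)
  W <- mean(vars)
  means <- colMeans(m)
  var_plus <- (n - 1) / n * W + stats::var(means)
  if (!is.finite(var_plus) || var_plus == 0) return(NA_real_)
  max_lag <- min(n - 1, 500)
  acov <- vapply(seq_len(k), function(j) {
    v <- m[, j] - means[j]
    stats::convolve(v, rev(v), type = "open")[n:(n + max_lag)] / n
  }, numeric(max_lag + 1))
  rho <- 1 - (W - rowMeans(acov)) / var_plus
  # Geyer initial monotone positive sequence on paired sums
  tau <- 1
  prev_pair <- Inf
  t <- 1
  while (t + 1 <= max_lag) {
    pair <- rho[t + 1] + rho[t + 2]
    if (!is.finite(pair) || pair < 0) break
    pair <- min(pair, prev_pair)
    tau <- tau + 2 * pair
    prev_pair <- pair
    t <- t + 2
  }
  (k * n) / tau
}

convergence_diagnostics <- function(draws, chain_id, par_names) {
  rhat <- vapply(seq_len(ncol(draws)),
                 function(j) split_rhat(draws[, j], chain_id), numeric(1))
  ess <- vapply(seq_len(ncol(draws)),
                function(j) ess_bulk(draws[, j], chain_id), numeric(1))
  tibble::tibble(parameter = par_names, rhat = rhat, ess_bulk = ess)
}
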