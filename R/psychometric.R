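#' Chance-floored Weibull (Quick) psychometric function
#'
#' Probability of a correct response as a function of stimulus onset
#' asynchrony (SOA) in a two-alternative task with a guessing floor and a
#' lapse rate:
#' \deqn{p(x) = \gamma + (1 - \gamma - \varepsilon)\,
#'   \left(1 - 2^{-(x/\theta)^{\beta}}\right)}
#' With zero lapse the function passes through 75% exactly at
#' \eqn{x = \theta}, so the threshold parameter is the SOA associated with
#' 75% accuracy.
#'
#' @param soa_s SOA in seconds, non-negative. Vectorized.
#' @param threshold_s Threshold parameter \eqn{\theta} in seconds (> 0).
#' @param shape Weibull shape \eqn{\beta} (> 0).
#' @param lapse Lapse rate \eqn{\varepsilon} in `[0, 0.5)`; accuracy is capped
#'   at `1 - lapse`.
#' @param chance Guessing floor \eqn{\gamma}; fixed at 0.5 for the
#'   same/different oddball task and validated as such.
#' @return Numeric vector of probabilities in `[chance, 1 - lapse]`.
#' @examples
#' pf_probability(0.06, threshold_s = 0.06, shape = 3, lapse = 0) # 0.75
#' pf_probability(0, threshold_s = 0.06, shape = 3)               # 0.5
#' @export
pf_probability <- function(soa_s, threshold_s, shape, lapse = 0.01,
                           chance = 0.5) {
  check_pf_params(threshold_s, shape, lapse, chance)
  if (!is.numeric(soa_s) || any(!is.finite(soa_s)) || any(soa_s < 0)) {
    stop("`soa_s` must be finite and non-negative.", call. = FALSE)
  }
  u <- (soa_s / threshold_s)^shape
  chance + (1 - chance - lapse) * (1 - 2^(-u))
}

#' Threshold as an exponentially saturating function of trial number
#'
#' The log threshold relaxes from its starting value `log_start` toward the
#' asymptote `log_asym` with a base-2 decay kernel:
#' \deqn{\theta(t) = \exp\!\left(A + (S - A)\, 2^{-(t-1)/10^{R}}\right)}
#' so that `10^log10_rate` is the number of trials over which half of the
#' log-threshold change is completed, and trial 1 sits exactly at the
#' starting threshold.
#'
#' @param t Trial index, >= 1 (integer or real). Vectorized.
#' @param log_start Natural log of the starting threshold (log-seconds), `S`.
#' @param log_asym Natural log of the asymptotic threshold (log-seconds), `A`.
#' @param log10_rate Base-10 log of the half-change time constant in
#'   trials, `R`.
#' @return Threshold in seconds.
#' @examples
#' threshold_at(1, log_start = log(0.5), log_asym = log(0.08), log10_rate = 1.7)
#' @export
threshold_at <- function(t, log_start, log_asym, log10_rate) {
  if (!is.numeric(t) || any(!is.finite(t)) || any(t < 1)) {
    stop("`t` must be finite and >= 1 (trials are 1-indexed).", call. = FALSE)
  }
  stopifnot(is.finite(log_start), is.finite(log_asym), is.finite(log10_rate))
  q <- 2^(-(t - 1) / 10^log10_rate)
  exp(log_asym + (log_start - log_asym) * q)
}

#' SOA at which the psychometric function reaches 75% accuracy
#'
#' Closed-form inverse of [pf_probability()] at p = 0.75:
#' \deqn{x_{75} = \theta \left(-\log_2\!\big(1 - 0.25/(0.5 -
#'   \varepsilon)\big)\right)^{1/\beta}}
#' With zero lapse this is the threshold parameter itself; with a nonzero
#' lapse the exact 75% point lies slightly above it. 75% is attainable only
#' while `lapse < 0.25`.
#'
#' @inheritParams pf_probability
#' @return SOA in seconds at which predicted accuracy is exactly 0.75.
#' @examples
#' solve_threshold75(0.1, shape = 3, lapse = 0)    # 0.1
#' solve_threshold75(0.1, shape = 3, lapse = 0.01) # slightly larger
#' @export
solve_threshold75 <- function(threshold_s, shape, lapse = 0.01,
                              chance = 0.5) {
  check_pf_params(threshold_s, shape, lapse, chance)
  if (any(lapse >= 0.25)) {
    stop("75% accuracy is unattainable when `lapse` >= 0.25.", call. = FALSE)
  }
  threshold_s * (-log2(1 - 0.25 / (0.5 - lapse)))^(1 / shape)
}

#' Magnitude of learning as an accuracy difference at a reference SOA
#'
#' The difference between ending and starting predicted accuracy, evaluated
#' at a fixed (typically the design-mean) SOA:
#' `pf(mean_soa | theta(t_end)) - pf(mean_soa | theta(t_start))`. Positive
#' values indicate that the threshold improved enough to raise accuracy at
#' that SOA.
#'
#' @inheritParams threshold_at
#' @inheritParams pf_probability
#' @param mean_soa_s Reference SOA in seconds (> 0).
#' @param t_start,t_end Trial indices bracketing the learning window;
#'   `t_end > t_start >= 1`.
#' @return Accuracy difference in `(-0.5 + lapse, 0.5 - lapse)`.
#' @examples
#' learning_magnitude(log(0.5), log(0.08), 1.7, shape = 3,
#'                    mean_soa_s = 0.159, t_start = 1, t_end = 200)
#' @export
learning_magnitude <- function(log_start, log_asym, log10_rate, shape,
                               lapse = 0.01, mean_soa_s, t_start = 1,
                               t_end = 200, chance = 0.5) {
  if (any(mean_soa_s <= 0)) {
    stop("`mean_soa_s` must be positive.", call. = FALSE)
  }
  if (any(t_end <= t_start) || any(t_start < 1)) {
    stop("need `t_end` > `t_start` >= 1.", call. = FALSE)
  }
  th0 <- threshold_at(t_start, log_start, log_asym, log10_rate)
  th1 <- threshold_at(t_end, log_start, log_asym, log10_rate)
  pf_probability(mean_soa_s, th1, shape, lapse, chance) -
    pf_probability(mean_soa_s, th0, shape, lapse, chance)
}

check_pf_params <- function(threshold_s, shape, lapse, chance) {
  if (!all(is.finite(threshold_s)) || any(threshold_s <= 0)) {
    stop("`threshold_s` must be finite and > 0.", call. = FALSE)
  }
  if (!all(is.finite(shape)) || any(shape <= 0)) {
    stop("`shape` must be finite and > 0.", call. = FALSE)
  }
  if (!all(is.finite(lapse)) || any(lapse < 0) || any(lapse >= 0.5)) {
    stop("`lapse` must lie in [0, 0.5).", call. = FALSE)
  }
  if (any(chance != 0.5)) {
    stop("`chance` is fixed at 0.5 for this task.", call. = FALSE)
  }
  invisible(TRUE)
}
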