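#' Exact one-tailed binomial p-value against chance
#'
#' \eqn{P(X \ge k)} for \eqn{X \sim \mathrm{Binomial}(n, 0.5)}, the
#' probability of observing at least `n_correct` successes under guessing.
#' Computed from the exact binomial tail, not a normal approximation.
#'
#' @param n_correct Number of correct responses (0..n_trials). Vectorized.
#' @param n_trials Number of trials.
#' @return Upper-tail p-value(s) in `[0, 1]`.
#' @export
binomial_screen_p <- function(n_correct, n_trials) {
  stopifnot(all(n_correct >= 0), all(n_correct <= n_trials))
  stats::pbinom(n_correct - 1, n_trials, 0.5, lower.tail = FALSE)
}

#' Exclude participants performing at chance
#'
#' For each participant, tests whether overall accuracy is significantly
#' above 50% with an exact one-tailed binomial test:
#' \eqn{p = P(X \ge k)} for \eqn{X \sim \mathrm{Binomial}(n, 0.5)}, computed
#' from the exact tail (no normal approximation). A participant is included
#' when `p < alpha`. The test uses all of a participant's trials; run this
#' before any trial-window truncation.
#'
#' @param records A trials data frame with `participant_id` and `correct`.
#' @param alpha Significance level (strict inequality), default 0.05.
#' @return A tibble with one row per participant: `participant_id`,
#'   `n_trials`, `n_correct`, `one_tailed_p`, `included`.
#' @examples
#' sim <- simulate_experiment(design_spec(n_per_cell = 2, trials_per_block = 30,
#'                                        seed = 1))
#' exclude_at_chance(sim$trials)
#' @export
exclude_at_chance <- function(records, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  if (any(is.na(records$correct))) {
    records <- dplyr::filter(records, !is.na(.data$correct))
  }
  out <- records |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(
      n_trials = dplyr::n(),
      n_correct = sum(.data$correct),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      one_tailed_p = binomial_screen_p(.data$n_correct, .data$n_trials),
      included = .data$one_tailed_p < alpha
    )
  if (any(out$n_trials == 0)) {
    warning("participant(s) with zero trials excluded; p undefined.")
    out$one_tailed_p[out$n_trials == 0] <- NA_real_
    out$included[out$n_trials == 0] <- FALSE
  }
  out
}

#' Restrict records to the first trials of each participant
#'
#' Retains trials with index `<= max_trial`, leaving per-participant trial
#' indices unchanged. The default window of 200 trials matches analyses
#' that drop a late-session performance decrement; `max_trial = Inf` keeps
#' everything (the all-trials sensitivity mode).
#'
#' @param records A trials data frame with a `trial` column.
#' @param max_trial Largest trial index to keep (>= 1); may be `Inf`.
#' @return The filtered tibble.
#' @export
truncate_trials <- function(records, max_trial = 200) {
  stopifnot(max_trial >= 1)
  dplyr::filter(records, .data$trial <= max_trial)
}

#' Per-cell inclusion counts after screening
#'
#' Cross-tabulates included participants by age group and condition,
#' mirroring the usual sample-size table of a 2 x 3 design.
#'
#' @param results Output of [exclude_at_chance()].
#' @param records The trials data frame the screening was computed from
#'   (used to look up each participant's cell).
#' @return A tibble with one row per age group and one column per condition.
#' @export
screening_summary <- function(results, records) {
  cells <- records |>
    dplyr::distinct(.data$participant_id, .data$age_group, .data$condition)
  results |>
    dplyr::left_join(cells, by = "participant_id") |>
    dplyr::filter(.data$included) |>
    dplyr::count(.data$age_group, .data$condition) |>
    tidyr::pivot_wider(names_from = "condition", values_from = "n",
                       values_fill = 0L)
}
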