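#' Experimental design specification for the simulator
#'
#' Describes a two-age-group, three-condition texture oddball detection
#' design: each participant completes `n_blocks` blocks of
#' `trials_per_block` trials, each trial showing the stimulus at one of a
#' fixed set of SOAs followed by a mask, with an oddball element present on
#' a fixed fraction of trials.
#'
#' @param n_per_cell Participants per age-group x condition cell.
#' @param n_blocks Number of blocks.
#' @param trials_per_block Trials per block.
#' @param soa_levels_ms SOA levels in milliseconds, strictly positive and
#'   sorted.
#' @param oddball_fraction Fraction of trials with the oddball present, in
#'   (0, 1).
#' @param balanced_soa If `TRUE`, SOA levels are assigned in shuffled
#'   balanced sets within each block; if `FALSE` (default) each trial draws
#'   its SOA uniformly at random from the levels.
#' @param seed Optional integer seed applied by [simulate_experiment()].
#' @return A `pl_design` list.
#' @export
design_spec <- function(n_per_cell = 24, n_blocks = 2, trials_per_block = 210,
                        soa_levels_ms = c(15, 30, 60, 90, 120, 300, 500),
                        oddball_fraction = 0.5, balanced_soa = FALSE,
                        seed = NULL) {
  stopifnot(
    n_per_cell >= 1, n_blocks >= 1, trials_per_block >= 1,
    n_per_cell == as.integer(n_per_cell),
    all(soa_levels_ms > 0), !is.unsorted(soa_levels_ms),
    oddball_fraction > 0, oddball_fraction < 1
  )
  structure(
    list(
      n_per_cell = as.integer(n_per_cell),
      n_blocks = as.integer(n_blocks),
      trials_per_block = as.integer(trials_per_block),
      soa_levels_ms = as.numeric(soa_levels_ms),
      oddball_fraction = oddball_fraction,
      balanced_soa = isTRUE(balanced_soa),
      seed = if (!is.null(seed)) as.integer(seed)
    ),
    class = "pl_design"
  )
}

#' Ground-truth population parameters for the simulator
#'
#' Fixed effects act on the three components of change -- asymptotic
#' log threshold (`A`), starting log threshold (`S`) and log10 half-change
#' rate (`R`) -- under the same coding the models use: age is -0.5 (child)
#' / +0.5 (adult), arousal is -0.5 (control) / +0.5 (stress and positive),
#' and valence is a monotonic effect over stress < control < positive with
#' cumulative simplex weights `zeta`. Defaults are round values on the
#' scales typical of this task (adult asymptote near exp(-2.7) s \eqn{\approx}
#' 67 ms; half-change after ~50 trials) with zero condition effects.
#'
#' @param a_intercept,s_intercept,r_intercept Component intercepts:
#'   log-seconds for `A` and `S`, log10 trials for `R`.
#' @param a_age,s_age,r_age Age effects (+ = larger for adults).
#' @param a_arousal,s_arousal,r_arousal Arousal effects.
#' @param a_valence,s_valence,r_valence Total monotonic valence effects
#'   (contribution at level x is the coefficient times the cumulative sum of
#'   `zeta` up to x).
#' @param zeta Valence simplex (two non-negative increments summing to 1).
#' @param sigma_a,sigma_s,sigma_r,sigma_shape By-participant random-effect
#'   SDs (on the link scales).
#' @param log_shape Intercept of the log Weibull shape.
#' @param lapse Lapse rate in `[0, 0.5)`.
#' @param fraction_at_chance Proportion of participants who respond at
#'   chance on every trial (exercises the exclusion filter), in `[0, 1)`.
#' @param block2_offset_a Optional additive offset on `A` in block 2 and
#'   later (e.g., for sensitivity studies of between-block interventions);
#'   0 by default.
#' @return A `pl_truth` list.
#' @export
ground_truth <- function(a_intercept = -2.4, s_intercept = 0.6,
                         r_intercept = 1.7,
                         a_age = -0.6, s_age = 1.0, r_age = 0,
                         a_arousal = 0, s_arousal = 0, r_arousal = 0,
                         a_valence = 0, s_valence = 0, r_valence = 0,
                         zeta = c(0.5, 0.5),
                         sigma_a = 0.5, sigma_s = 0.8, sigma_r = 0.5,
                         sigma_shape = 0.2, log_shape = 1.2, lapse = 0.01,
                         fraction_at_chance = 0.1, block2_offset_a = 0) {
  stopifnot(
    length(zeta) == 2, all(zeta >= 0), abs(sum(zeta) - 1) < 1e-8,
    sigma_a >= 0, sigma_s >= 0, sigma_r >= 0, sigma_shape >= 0,
    lapse >= 0, lapse < 0.5,
    fraction_at_chance >= 0, fraction_at_chance < 1
  )
  structure(
    list(
      a_intercept = a_intercept, s_intercept = s_intercept,
      r_intercept = r_intercept,
      a_age = a_age, s_age = s_age, r_age = r_age,
      a_arousal = a_arousal, s_arousal = s_arousal, r_arousal = r_arousal,
      a_valence = a_valence, s_valence = s_valence, r_valence = r_valence,
      zeta = as.numeric(zeta),
      sigma_a = sigma_a, sigma_s = sigma_s, sigma_r = sigma_r,
      sigma_shape = sigma_shape, log_shape = log_shape, lapse = lapse,
      fraction_at_chance = fraction_at_chance,
      block2_offset_a = block2_offset_a
    ),
    class = "pl_truth"
  )
}

# design coding shared by simulator and models
age_code <- function(age_group) ifelse(age_group == "adult", 0.5, -0.5)
arousal_code <- function(condition) ifelse(condition == "control", -0.5, 0.5)
valence_level <- function(condition) {
  # monotone ordering: stress (0) < control (1) < positive (2)
  c(stress = 0L, control = 1L, positive = 2L)[condition]
}
cum_zeta <- function(zeta) c(0, zeta[1], 1)

#' Simulate a full experiment with known ground truth
#'
#' Draws by-participant random effects, evolves each participant's threshold
#' over trials with [threshold_at()], converts SOA to accuracy with
#' [pf_probability()], and draws Bernoulli correctness. A
#' `fraction_at_chance` subset of participants responds correctly with
#' probability 0.5 on every trial regardless of SOA. Oddball-present and
#' oddball-absent trials share the same accuracy model.
#'
#' @param design A [design_spec()].
#' @param truth A [ground_truth()].
#' @return A `pl_simulation` list with elements `trials` (one row per trial:
#'   `participant_id`, `age_group`, `condition`, `block`, `trial`, `soa_ms`,
#'   `oddball_present`, `correct`) and `participants` (the per-participant
#'   realized ground truth, including the at-chance flag).
#' @examples
#' sim <- simulate_experiment(design_spec(n_per_cell = 2, trials_per_block = 20,
#'                                        seed = 1))
#' head(sim$trials)
#' @export
simulate_experiment <- function(design = design_spec(),
                                truth = ground_truth()) {
  stopifnot(inherits(design, "pl_design"), inherits(truth, "pl_truth"))
  if (!is.null(design$seed)) set.seed(design$seed)

  cells <- tidyr::expand_grid(
    age_group = c("child", "adult"),
    condition = c("control", "positive", "stress")
  )
  participants <- tidyr::expand_grid(cells, rep = seq_len(design$n_per_cell)) |>
    dplyr::mutate(
      participant_id = sprintf(
        "%s_%s_%02d", substr(.data$age_group, 1, 2),
        substr(.data$condition, 1, 3), .data$rep
      )
    ) |>
    dplyr::select(-"rep")

  P <- nrow(participants)
  cz <- cum_zeta(truth$zeta)
  xv <- cz[valence_level(participants$condition) + 1L]
  xa <- age_code(participants$age_group)
  xr <- arousal_code(participants$condition)

  participants <- participants |>
    dplyr::mutate(
      log_asym = truth$a_intercept + truth$a_age * xa +
        truth$a_arousal * xr + truth$a_valence * xv +
        truth$sigma_a * stats::rnorm(P),
      log_start = truth$s_intercept + truth$s_age * xa +
        truth$s_arousal * xr + truth$s_valence * xv +
        truth$sigma_s * stats::rnorm(P),
      log10_rate = truth$r_intercept + truth$r_age * xa +
        truth$r_arousal * xr + truth$r_valence * xv +
        truth$sigma_r * stats::rnorm(P),
      shape = exp(truth$log_shape + truth$sigma_shape * stats::rnorm(P)),
      at_chance = stats::runif(P) < truth$fraction_at_chance
    )

  n_trials <- design$n_blocks * design$trials_per_block
  draw_soa <- function() {
    if (design$balanced_soa) {
      per_block <- function() {
        lv <- design$soa_levels_ms
        sample(rep(lv, length.out = design$trials_per_block))
      }
      unlist(replicate(design$n_blocks, per_block(), simplify = FALSE))
    } else {
      sample(design$soa_levels_ms, n_trials, replace = TRUE)
    }
  }

  trials <- purrr::pmap_dfr(participants, function(participant_id, age_group,
                                                   condition, log_asym,
                                                   log_start, log10_rate,
                                                   shape, at_chance, ...) {
    t_idx <- seq_len(n_trials)
    block <- rep(seq_len(design$n_blocks), each = design$trials_per_block)
    soa_ms <- draw_soa()
    la <- log_asym + ifelse(block >= 2, truth$block2_offset_a, 0)
    th <- threshold_at(t_idx, log_start, la, log10_rate)
    p <- if (at_chance) {
      rep(0.5, n_trials)
    } else {
      pf_probability(soa_ms / 1000, th, shape, truth$lapse)
    }
    tibble::tibble(
      participant_id = participant_id,
      age_group = age_group,
      condition = condition,
      block = block,
      trial = t_idx,
      soa_ms = soa_ms,
      oddball_present = stats::runif(n_trials) < design$oddball_fraction,
      correct = stats::runif(n_trials) < p
    )
  })

  structure(
    list(trials = trials, participants = participants, design = design,
         truth = truth),
    class = "pl_simulation"
  )
}

#' @export
print.pl_simulation <- function(x, ...) {
  cat("<pl_simulation>: ", nrow(x$participants), " participants, ",
      nrow(x$trials), " trials (",
      x$design$n_blocks, " block(s) x ", x$design$trials_per_block,
      " trials)\n", sep = "")
  invisible(x)
}

#' Centered moving proportion of correct responses
#'
#' A model-free smoother of group accuracy over trials: for every trial
#' index and group (age group x condition), the proportion correct among
#' all trials whose index falls inside a centered window. Edge positions use
#' truncated windows. With `window = 1` this is the raw per-trial group
#' proportion.
#'
#' @param records A trials data frame (as produced by
#'   [simulate_experiment()]).
#' @param window Window width in trials (>= 1).
#' @return A tibble with `age_group`, `condition`, `trial`, `n` (trials in
#'   the window) and `accuracy`.
#' @export
smooth_accuracy <- function(records, window = 15) {
  stopifnot(window >= 1, window == as.integer(window))
  if (nrow(records) == 0) {
    warning("no trials supplied; returning empty smoother output.")
    return(tibble::tibble(age_group = character(), condition = character(),
                          trial = integer(), n = integer(),
                          accuracy = numeric()))
  }
  lo_off <- floor((window - 1) / 2)
  hi_off <- ceiling((window - 1) / 2)
  records |>
    dplyr::group_by(.data$age_group, .data$condition, .data$trial) |>
    dplyr::summarise(k = sum(.data$correct), n = dplyr::n(),
                     .groups = "drop") |>
    dplyr::group_by(.data$age_group, .data$condition) |>
    dplyr::group_modify(function(df, key) {
      df <- dplyr::arrange(df, .data$trial)
      ks <- cumsum(df$k)
      ns <- cumsum(df$n)
      idx_lo <- findInterval(df$trial - lo_off - 1L, df$trial)
      idx_hi <- findInterval(df$trial + hi_off, df$trial)
      k_win <- ks[idx_hi] - ifelse(idx_lo > 0, ks[pmax(idx_lo, 1L)], 0)
      n_win <- ns[idx_hi] - ifelse(idx_lo > 0, ns[pmax(idx_lo, 1L)], 0)
      tibble::tibble(trial = df$trial, n = as.integer(n_win),
                     accuracy = k_win / n_win)
    }) |>
    dplyr::ungroup()
}

#' Write a simulated experiment to disk as plain text
#'
#' Emits the long-format trials CSV, the per-participant ground-truth CSV,
#' and a small JSON manifest recording paths and the seed.
#'
#' @param sim A `pl_simulation`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest list.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "pl_simulation"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  trials_path <- file.path(dir, "trials.csv")
  truth_path <- file.path(dir, "participants.csv")
  utils::write.csv(sim$trials, trials_path, row.names = FALSE)
  utils::write.csv(sim$participants, truth_path, row.names = FALSE)
  manifest <- list(
    trials = trials_path, participants = truth_path,
    seed = sim$design$seed, n_participants = nrow(sim$participants),
    n_trials = nrow(sim$trials)
  )
  jsonlite::write_json(manifest, file.path(dir, "simulation_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(manifest)
}
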