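#' Prior settings for the hierarchical learning model
#'
#' Weakly informative defaults scaled to the task: SOAs span 15--500 ms, so
#' log thresholds live within a few units of log(0.1 s), and with a few
#' hundred trials the half-change constant plausibly spans 1--1000 trials.
#' Component intercepts get their own locations; all other fixed effects
#' (age, arousal, valence, interactions) share a zero-centered normal.
#'
#' @param a_intercept,s_intercept,r_intercept Length-2 `c(mean, sd)` normal
#'   priors for the asymptote (log-seconds), start (log-seconds) and rate
#'   (log10 trials) intercepts.
#' @param coef_sd SD of the zero-centered normal prior on all non-intercept
#'   fixed effects, including monotonic-valence total coefficients.
#' @param shape Normal prior `c(mean, sd)` on the log Weibull shape
#'   intercept.
#' @param sigma_sd Scale of the half-normal prior on all random-effect SDs.
#' @param lapse_beta Beta prior `c(a, b)` on `2 * lapse` used only when the
#'   lapse is estimated.
#' @return A `pl_priors` list.
#' @export
pl_priors <- function(a_intercept = c(-2.5, 1), s_intercept = c(0, 1.5),
                      r_intercept = c(log10(50), 0.7), coef_sd = 1,
                      shape = c(log(3), 0.5), sigma_sd = 1,
                      lapse_beta = c(2, 60)) {
  stopifnot(
    a_intercept[2] > 0, s_intercept[2] > 0, r_intercept[2] > 0,
    coef_sd > 0, shape[2] > 0, sigma_sd > 0, all(lapse_beta > 0)
  )
  structure(
    list(a_intercept = a_intercept, s_intercept = s_intercept,
         r_intercept = r_intercept, coef_sd = coef_sd, shape = shape,
         sigma_sd = sigma_sd, lapse_beta = lapse_beta),
    class = "pl_priors"
  )
}

#' Model specification
#'
#' Four model structures are supported, mirroring the analysis plan of a
#' 2 (age) x 3 (condition) learning experiment:
#' \describe{
#'   \item{`"full"`}{Both age groups and all conditions. Fixed effects of
#'     age, arousal (coded -0.5 control / +0.5 stress and positive) and a
#'     three-level monotonic valence effect (stress < control < positive,
#'     cumulative simplex weights) on each component of change, optionally
#'     with age interactions.}
#'   \item{`"arousal"`}{A single age group, all conditions, a binary
#'     arousal contrast on each component.}
#'   \item{`"valence"`}{A single age group, stress and positive conditions
#'     only, a binary valence contrast (-0.5 stress / +0.5 positive).}
#'   \item{`"null"`}{No condition effects; by-participant random effects
#'     are retained. The comparison partner of `"arousal"`/`"valence"`.}
#' }
#' All models estimate by-participant random effects on the three
#' components of change and on the log PF shape.
#'
#' @param model One of `"full"`, `"arousal"`, `"valence"`, `"null"`.
#' @param age `"both"` (full model) or `"child"`/`"adult"` (per-age
#'   models). `"both"` with a per-age model fits the pooled data without an
#'   age term and is primarily useful for testing.
#' @param include_interactions Full model only: include age x arousal and
#'   age x valence interactions (the age x valence term shares the
#'   per-component simplex with the valence main effect).
#' @param conditions Conditions retained; defaults to stress/positive for
#'   `"valence"` and all three otherwise.
#' @param lapse Fixed lapse rate used when `estimate_lapse = FALSE`.
#' @param estimate_lapse Estimate a common lapse rate instead of fixing it.
#' @param priors A [pl_priors()] object.
#' @return A `pl_model_spec` list.
#' @export
model_spec <- function(model = c("full", "arousal", "valence", "null"),
                       age = NULL, include_interactions = TRUE,
                       conditions = NULL, lapse = 0.01,
                       estimate_lapse = FALSE, priors = pl_priors()) {
  model <- match.arg(model)
  if (is.null(age)) age <- if (model == "full") "both" else "both"
  age <- match.arg(age, c("both", "child", "adult"))
  if (model == "full" && age != "both") {
    stop("the full model uses both age groups.", call. = FALSE)
  }
  if (is.null(conditions)) {
    conditions <- if (model == "valence") c("stress", "positive")
                  else c("control", "positive", "stress")
  }
  stopifnot(lapse >= 0, lapse < 0.5, inherits(priors, "pl_priors"))
  structure(
    list(model = model, age = age,
         include_interactions = isTRUE(include_interactions) &&
           model == "full",
         conditions = conditions, lapse = lapse,
         estimate_lapse = isTRUE(estimate_lapse), priors = priors),
    class = "pl_model_spec"
  )
}

#' MCMC settings
#'
#' @param chains Number of HMC chains (run serially).
#' @param warmup Adaptation iterations per chain (discarded).
#' @param iter Post-warmup draws per chain.
#' @param target_accept Dual-averaging acceptance target.
#' @param max_leapfrog Maximum leapfrog steps per transition (the realized
#'   number is jittered uniformly on `1:max_leapfrog`).
#' @param init_step Initial leapfrog step size.
#' @return A `pl_mcmc` list.
#' @export
mcmc_control <- function(chains = 2, warmup = 500, iter = 500,
                         target_accept = 0.8, max_leapfrog = 64,
                         init_step = 0.05) {
  stopifnot(chains >= 1, warmup >= 50, iter >= 10,
            target_accept > 0.5, target_accept < 1, max_leapfrog >= 1)
  structure(list(chains = as.integer(chains), warmup = as.integer(warmup),
                 iter = as.integer(iter), target_accept = target_accept,
                 max_leapfrog = as.integer(max_leapfrog),
                 init_step = init_step),
            class = "pl_mcmc")
}

# subset records per spec and validate them for modelling
subset_for_spec <- function(records, spec) {
  out <- records
  if (spec$age != "both") out <- dplyr::filter(out, .data$age_group == spec$age)
  out <- dplyr::filter(out, .data$condition %in% spec$conditions)
  if (nrow(out) == 0) stop("no trials left after subsetting.", call. = FALSE)
  if (any(is.na(out$correct))) {
    stop("missing correctness values; clean the records first.",
         call. = FALSE)
  }
  if (any(!is.finite(out$soa_ms)) || any(out$soa_ms <= 0)) {
    stop("SOA values must be positive and finite.", call. = FALSE)
  }
  out
}

# Build the data list consumed by the compiled log density, plus parameter
# names and the fixed-effect term table.
prepare_model_data <- function(records, spec) {
  stopifnot(inherits(spec, "pl_model_spec"))
  records <- subset_for_spec(records, spec)

  participants <- records |>
    dplyr::distinct(.data$participant_id, .data$age_group, .data$condition) |>
    dplyr::arrange(.data$participant_id)
  if (anyDuplicated(participants$participant_id)) {
    stop("a participant appears in more than one design cell.",
         call. = FALSE)
  }
  P <- nrow(participants)
  if (P < 2) {
    stop("random effects require at least 2 participants per model.",
         call. = FALSE)
  }

  xa <- age_code(participants$age_group)
  xr <- arousal_code(participants$condition)
  has_mono <- spec$model == "full"
  mono_int <- has_mono && spec$include_interactions

  X <- switch(spec$model,
    full = {
      cols <- cbind(Intercept = 1, age = xa, arousal = xr)
      if (mono_int) cols <- cbind(cols, `age × arousal` = xa * xr)
      cols
    },
    arousal = cbind(Intercept = 1, arousal = xr),
    valence = cbind(
      Intercept = 1,
      valence = ifelse(participants$condition == "positive", 0.5, -0.5)
    ),
    null = cbind(Intercept = rep(1, P))
  )
  K <- ncol(X)

  pr <- spec$priors
  prior_b_mean <- matrix(0, K, 3)
  prior_b_sd <- matrix(pr$coef_sd, K, 3)
  prior_b_mean[1, ] <- c(pr$a_intercept[1], pr$s_intercept[1],
                         pr$r_intercept[1])
  prior_b_sd[1, ] <- c(pr$a_intercept[2], pr$s_intercept[2],
                       pr$r_intercept[2])

  pid <- match(records$participant_id, participants$participant_id) - 1L

  data <- list(
    y = as.integer(records$correct),
    x = records$soa_ms / 1000,
    tt = as.numeric(records$trial),
    pid = pid,
    P = P,
    X = X,
    has_mono = has_mono,
    mono_int = mono_int,
    est_lapse = spec$estimate_lapse,
    vlev = if (has_mono) as.integer(valence_level(participants$condition))
           else integer(P),
    xage = xa,
    lapse = spec$lapse,
    prior_b_mean = prior_b_mean,
    prior_b_sd = prior_b_sd,
    prior_bv_sd = pr$coef_sd,
    prior_shape_mean = pr$shape[1],
    prior_shape_sd = pr$shape[2],
    prior_sigma_sd = pr$sigma_sd,
    prior_lapse_a = pr$lapse_beta[1],
    prior_lapse_b = pr$lapse_beta[2]
  )

  comp <- c("Asym", "Start", "Rate")
  fixed <- unlist(lapply(comp, function(cm) {
    paste0(cm, ": ", colnames(X))
  }))
  nm <- fixed
  if (has_mono) nm <- c(nm, paste0(comp, ": valence"))
  if (mono_int) nm <- c(nm, paste0(comp, ": age × valence"))
  if (has_mono) nm <- c(nm, paste0("zeta1_", c("Asym", "Start", "Rate")))
  nm <- c(nm, "PF shape: Intercept",
          paste0("log_sigma_", c("Asym", "Start", "Rate", "shape")))
  ids <- participants$participant_id
  nm <- c(nm,
          paste0("z_Asym[", ids, "]"), paste0("z_Start[", ids, "]"),
          paste0("z_Rate[", ids, "]"), paste0("z_shape[", ids, "]"))
  if (spec$estimate_lapse) nm <- c(nm, "logit_2lapse")

  fixed_terms <- c(fixed,
                   if (has_mono) paste0(comp, ": valence"),
                   if (mono_int) paste0(comp, ": age × valence"),
                   "PF shape: Intercept")

  list(data = data, participants = participants, par_names = nm,
       fixed_terms = fixed_terms, records = records)
}

# display order mirroring the coefficient tables: grouped by component with
# interactions next to their main effects
order_fixed_terms <- function(terms) {
  comp <- c("Asym", "Start", "Rate")
  within <- c("Intercept", "age", "arousal", "age × arousal", "valence",
              "age × valence")
  wanted <- c(as.vector(t(outer(comp, within, paste, sep = ": "))),
              "PF shape: Intercept")
  terms[order(match(terms, wanted))]
}
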