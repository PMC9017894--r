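#' Base-3 log Bayes factor from two log marginal likelihoods
#'
#' \eqn{\log_3 \mathrm{BF} = (\log \mathrm{ML}_{effect} -
#' \log \mathrm{ML}_{null}) / \ln 3}. On this scale, values below -1
#' indicate at least moderate evidence for the simpler (null) model and
#' values above +1 at least moderate evidence for the more complex model;
#' the boundary itself is classified with the strict inequalities, so
#' exactly +1 or -1 counts as equivocal.
#'
#' @param log_ml_effect,log_ml_null Log marginal likelihoods (finite), or
#'   `pl_bridge` objects.
#' @param label Optional label for the comparison.
#' @return A one-row tibble of class `pl_comparison` with the two log
#'   marginal likelihoods, `log3_bf`, the combined `mc_error` (on the
#'   log3 scale, when available) and a `verdict`.
#' @export
bayes_factor_log3 <- function(log_ml_effect, log_ml_null, label = NULL) {
  err <- c(0, 0)
  if (inherits(log_ml_effect, "pl_bridge")) {
    err[1] <- log_ml_effect$mc_error
    log_ml_effect <- log_ml_effect$log_ml
  }
  if (inherits(log_ml_null, "pl_bridge")) {
    err[2] <- log_ml_null$mc_error
    log_ml_null <- log_ml_null$log_ml
  }
  if (!is.finite(log_ml_effect) || !is.finite(log_ml_null)) {
    stop("log marginal likelihoods must be finite.", call. = FALSE)
  }
  log3 <- (log_ml_effect - log_ml_null) / log(3)
  verdict <- if (log3 < -1) "supports-simpler"
             else if (log3 > 1) "supports-complex"
             else "equivocal"
  out <- tibble::tibble(
    label = label %||% NA_character_,
    log_ml_effect = log_ml_effect,
    log_ml_null = log_ml_null,
    log3_bf = log3,
    mc_error = sqrt(sum(err^2)) / log(3),
    verdict = verdict
  )
  class(out) <- c("pl_comparison", class(out))
  out
}

#' Effect-versus-null model comparisons for each age and affective dimension
#'
#' Fits, for each age group crossed with each affective dimension, a model
#' with the condition main effect on every component of change and a null
#' model with the effect removed (random effects retained), then compares
#' the pair by bridge-sampling Bayes factors. Valence pairs use the stress
#' and positive conditions only; arousal pairs use all three conditions.
#' Both models of a pair are fit to the identical data subset.
#'
#' @param records Screened, truncated trials containing both age groups (a
#'   pair whose data subset is missing is skipped with a warning).
#' @param mcmc An [mcmc_control()] shared by the eight fits.
#' @param seed Integer seed; per-fit seeds are derived deterministically.
#' @param priors A [pl_priors()].
#' @param dimensions Affective dimensions to compare (default both).
#' @param lapse,estimate_lapse Lapse handling passed to [model_spec()].
#' @param keep_fits Return the eight fitted models as an attribute.
#' @param quiet Suppress progress messages.
#' @return A tibble of class `pl_comparisons` with one row per comparison
#'   (label, age, dimension, log marginal likelihoods, `log3_bf`,
#'   `mc_error`, `verdict`).
#' @export
run_comparison_suite <- function(records, mcmc = mcmc_control(), seed = 1,
                                 priors = pl_priors(), lapse = 0.01,
                                 estimate_lapse = FALSE,
                                 dimensions = c("arousal", "valence"),
                                 keep_fits = FALSE, quiet = TRUE) {
  dimensions <- match.arg(dimensions, several.ok = TRUE)
  grid <- tidyr::expand_grid(age = c("child", "adult"),
                             dimension = dimensions)
  fits <- list()
  rows <- purrr::pmap_dfr(grid, function(age, dimension) {
    conds <- if (dimension == "valence") c("stress", "positive")
             else c("control", "positive", "stress")
    sub <- dplyr::filter(records, .data$age_group == age,
                         .data$condition %in% conds)
    have <- unique(sub$condition)
    if (length(have) < length(conds) || nrow(sub) == 0) {
      warning(sprintf("skipping %s/%s: missing design cells.", age,
                      dimension), call. = FALSE)
      return(tibble::tibble())
    }
    pair_seed <- seed + 17L * match(age, c("child", "adult")) +
      31L * match(dimension, c("arousal", "valence"))
    spec_eff <- model_spec(dimension, age = age, lapse = lapse,
                           estimate_lapse = estimate_lapse, priors = priors)
    spec_null <- model_spec("null", age = age, conditions = conds,
                            lapse = lapse, estimate_lapse = estimate_lapse,
                            priors = priors)
    if (!quiet) message(sprintf("fitting %s / %s ...", age, dimension))
    fit_eff <- fit_learning_model(sub, spec_eff, mcmc, seed = pair_seed)
    fit_null <- fit_learning_model(sub, spec_null, mcmc,
                                   seed = pair_seed + 1L)
    ml_eff <- log_marginal_likelihood(fit_eff, seed = pair_seed + 2L,
                                      min_ess = 0)
    ml_null <- log_marginal_likelihood(fit_null, seed = pair_seed + 3L,
                                       min_ess = 0)
    if (keep_fits) {
      fits[[paste(age, dimension, "effect", sep = "_")]] <<- fit_eff
      fits[[paste(age, dimension, "null", sep = "_")]] <<- fit_null
    }
    bayes_factor_log3(ml_eff, ml_null,
                      label = paste(age, dimension, sep = " x "))  |>
      dplyr::mutate(age = age, dimension = dimension,
                    .after = "label")
  })
  class(rows) <- c("pl_comparisons", setdiff(class(rows), "pl_comparison"))
  if (keep_fits) attr(rows, "fits") <- fits
  rows
}

`%||%` <- function(a, b) if (is.null(a)) b else a
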