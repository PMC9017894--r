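#' Pipeline configuration
#'
#' Bundles everything one analysis run needs: the data source (a simulated
#' design or an existing long-format trials CSV), the screening and
#' truncation settings, the model/prior settings, and the MCMC budget. All
#' randomness in a run flows from `seed`, expanded deterministically per
#' stage.
#'
#' @param seed Top-level integer seed.
#' @param design A [design_spec()] used when simulating.
#' @param truth A [ground_truth()] used when simulating.
#' @param input_csv Optional path to a trials CSV with columns
#'   `participant_id, age_group, condition, block, trial, soa_ms,
#'   oddball_present, correct`; when given, simulation is skipped.
#' @param alpha Screening significance level.
#' @param max_trial Truncation window (`Inf` for the all-trials
#'   sensitivity mode).
#' @param include_interactions Full-model age interactions.
#' @param lapse,estimate_lapse Lapse handling.
#' @param priors A [pl_priors()].
#' @param mcmc An [mcmc_control()].
#' @return A `pl_config` list.
#' @export
pl_config <- function(seed = 1, design = design_spec(),
                      truth = ground_truth(), input_csv = NULL,
                      alpha = 0.05, max_trial = 200,
                      include_interactions = TRUE, lapse = 0.01,
                      estimate_lapse = FALSE, priors = pl_priors(),
                      mcmc = mcmc_control()) {
  fail <- function(field, msg) {
    stop(sprintf("config error in `%s`: %s", field, msg), call. = FALSE)
  }
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed)) {
    fail("seed", "must be a single finite number")
  }
  if (!inherits(design, "pl_design")) fail("design", "not a design_spec()")
  if (!inherits(truth, "pl_truth")) fail("truth", "not a ground_truth()")
  if (!is.null(input_csv) && !file.exists(input_csv)) {
    fail("input_csv", "file does not exist")
  }
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    fail("alpha", "must lie in (0, 1)")
  }
  if (!is.numeric(max_trial) || max_trial < 1) {
    fail("max_trial", "must be >= 1 (may be Inf)")
  }
  if (!inherits(priors, "pl_priors")) fail("priors", "not a pl_priors()")
  if (!inherits(mcmc, "pl_mcmc")) fail("mcmc", "not an mcmc_control()")
  structure(
    list(seed = as.integer(seed), design = design, truth = truth,
         input_csv = input_csv, alpha = alpha, max_trial = max_trial,
         include_interactions = isTRUE(include_interactions),
         lapse = lapse, estimate_lapse = isTRUE(estimate_lapse),
         priors = priors, mcmc = mcmc),
    class = "pl_config"
  )
}

read_trials_csv <- function(path) {
  tr <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  needed <- c("participant_id", "age_group", "condition", "block", "trial",
              "soa_ms", "correct")
  missing <- setdiff(needed, names(tr))
  if (length(missing)) {
    stop("data validation: trials CSV lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tr$correct <- as.logical(tr$correct)
  if (any(is.na(tr$correct))) {
    stop("data validation: `correct` contains missing values.",
         call. = FALSE)
  }
  if (any(!is.finite(tr$soa_ms)) || any(tr$soa_ms <= 0)) {
    stop("data validation: `soa_ms` must be positive.", call. = FALSE)
  }
  tr
}

#' Write coefficient tables and the comparison report
#'
#' Renders each fitted model's fixed-effect summary as a CSV with columns
#' `term, estimate, conf.low, conf.high, reliable` (the numeric cells are
#' exactly the fit summaries -- no recomputation) and the comparisons as a
#' JSON report carrying log marginal likelihoods, base-3 log Bayes factors
#' and verdicts.
#'
#' @param fits Named list of `pl_fit` objects.
#' @param comparisons A `pl_comparisons` tibble, or `NULL`.
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
render_tables <- function(fits, comparisons, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  for (nm in names(fits)) {
    p <- file.path(dir, paste0("coefficients_", nm, ".csv"))
    utils::write.csv(summarize_fixed_effects(fits[[nm]]), p,
                     row.names = FALSE)
    paths <- c(paths, p)
  }
  p <- file.path(dir, "comparisons.json")
  if (is.null(comparisons) || nrow(comparisons) == 0) {
    jsonlite::write_json(list(comparisons = list(),
                              note = "no comparisons computed"),
                         p, auto_unbox = TRUE, pretty = TRUE)
  } else {
    jsonlite::write_json(as.list(tibble::as_tibble(comparisons)), p,
                         pretty = TRUE, digits = NA)
  }
  invisible(c(paths, p))
}

#' Run the full analysis pipeline
#'
#' Sequences simulate (or load) -> screen -> truncate -> fit the full model
#' -> fit the four per-age effect/null pairs with bridge-sampling
#' comparisons -> render tables, writing a manifest that records the config
#' snapshot, derived stage seeds, file hashes and timings. Re-running with
#' an identical config reproduces the outputs.
#'
#' @param config A [pl_config()].
#' @param out_dir Output directory.
#' @param stages Character subset of
#'   `c("data", "screen", "fit_full", "compare")`; later stages require
#'   earlier ones.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the manifest, trials, screening results,
#'   full-model fit and comparisons.
#' @export
run_pipeline <- function(config = pl_config(), out_dir,
                         stages = c("data", "screen", "fit_full",
                                    "compare"),
                         quiet = TRUE) {
  stopifnot(inherits(config, "pl_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  manifest <- list(
    package_version = as.character(utils::packageVersion("perceptlearn")),
    seed = config$seed,
    stage_seeds = list(data = config$seed, fit_full = config$seed + 100L,
                       compare = config$seed + 200L),
    started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    config = serialize_config(config),
    stages = list(), outputs = list()
  )
  results <- list()
  timer <- function(expr) {
    t0 <- Sys.time()
    val <- expr
    list(value = val,
         seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  }
  finish_stage <- function(name, seconds, files) {
    manifest$stages[[name]] <<- list(seconds = seconds, files = files)
    for (f in files) {
      manifest$outputs[[basename(f)]] <<-
        unname(tools::md5sum(f))
    }
    write_manifest(manifest, out_dir)
  }

  # -- data ----------------------------------------------------------------
  say("stage: data")
  st <- timer({
    if (is.null(config$input_csv)) {
      design <- config$design
      design$seed <- manifest$stage_seeds$data
      sim <- simulate_experiment(design, config$truth)
      write_simulation(sim, out_dir)
      sim$trials
    } else {
      read_trials_csv(config$input_csv)
    }
  })
  trials <- st$value
  results$trials <- trials
  data_files <- file.path(out_dir, c("trials.csv", "participants.csv"))
  finish_stage("data", st$seconds, data_files[file.exists(data_files)])
  if (!"screen" %in% stages) {
    return(invisible(c(results, list(manifest = manifest))))
  }

  # -- screening + truncation ---------------------------------------------
  say("stage: screen")
  st <- timer({
    screen <- exclude_at_chance(trials, alpha = config$alpha)
    utils::write.csv(screen, file.path(out_dir, "screening.csv"),
                     row.names = FALSE)
    utils::write.csv(screening_summary(screen, trials),
                     file.path(out_dir, "sample_sizes.csv"),
                     row.names = FALSE)
    screen
  })
  screen <- st$value
  results$screening <- screen
  kept <- screen$participant_id[screen$included]
  modelled <- trials |>
    dplyr::filter(.data$participant_id %in% kept) |>
    truncate_trials(max_trial = config$max_trial)
  results$modelled <- modelled
  finish_stage("screen", st$seconds,
               file.path(out_dir, c("screening.csv", "sample_sizes.csv")))
  if (!"fit_full" %in% stages) {
    return(invisible(c(results, list(manifest = manifest))))
  }

  # -- full model ----------------------------------------------------------
  say("stage: fit_full")
  st <- timer({
    spec <- model_spec("full",
                       include_interactions = config$include_interactions,
                       lapse = config$lapse,
                       estimate_lapse = config$estimate_lapse,
                       priors = config$priors)
    fit <- fit_learning_model(modelled, spec, config$mcmc,
                              seed = manifest$stage_seeds$fit_full)
    render_tables(list(full = fit), NULL, out_dir)
    utils::write.csv(fit$diagnostics,
                     file.path(out_dir, "diagnostics_full.csv"),
                     row.names = FALSE)
    fit
  })
  results$fit_full <- st$value
  finish_stage("fit_full", st$seconds,
               file.path(out_dir, c("coefficients_full.csv",
                                    "diagnostics_full.csv")))
  if (!"compare" %in% stages) {
    return(invisible(c(results, list(manifest = manifest))))
  }

  # -- per-age comparisons -------------------------------------------------
  say("stage: compare")
  st <- timer({
    cmp <- run_comparison_suite(modelled, mcmc = config$mcmc,
                                seed = manifest$stage_seeds$compare,
                                priors = config$priors,
                                lapse = config$lapse,
                                estimate_lapse = config$estimate_lapse,
                                keep_fits = TRUE, quiet = quiet)
    fits <- attr(cmp, "fits")
    eff <- fits[grepl("_effect$", names(fits))]
    render_tables(eff, cmp, out_dir)
    cmp
  })
  results$comparisons <- st$value
  cmp_files <- file.path(out_dir, c(
    paste0("coefficients_", names(attr(results$comparisons, "fits"))
           [grepl("_effect$", names(attr(results$comparisons, "fits")))],
           ".csv"),
    "comparisons.json"))
  finish_stage("compare", st$seconds, cmp_files[file.exists(cmp_files)])

  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  write_manifest(manifest, out_dir)
  results$manifest <- manifest
  invisible(results)
}

serialize_config <- function(config) {
  list(
    seed = config$seed,
    design = unclass(config$design),
    truth = unclass(config$truth),
    input_csv = config$input_csv,
    alpha = config$alpha,
    max_trial = if (is.finite(config$max_trial)) config$max_trial else "all",
    include_interactions = config$include_interactions,
    lapse = config$lapse, estimate_lapse = config$estimate_lapse,
    priors = unclass(config$priors),
    mcmc = unclass(config$mcmc)
  )
}

write_manifest <- function(manifest, out_dir) {
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null",
                       digits = NA)
  invisible(manifest)
}
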