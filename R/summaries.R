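# unconstrained parameter-vector layout; must mirror the compiled code
par_layout <- function(dat) {
  K <- ncol(dat$X)
  P <- dat$P
  off <- 0L
  take <- function(n) {
    idx <- off + seq_len(n)
    off <<- off + n
    idx
  }
  idx <- list(bA = take(K), bS = take(K), bR = take(K))
  if (dat$has_mono) idx$bv <- take(3L)
  if (dat$has_mono && dat$mono_int) idx$bav <- take(3L)
  if (dat$has_mono) idx$r <- take(3L)
  idx$bsh <- take(1L)
  idx$logsig <- take(4L)
  idx$zA <- take(P)
  idx$zS <- take(P)
  idx$zR <- take(P)
  idx$zsh <- take(P)
  if (dat$est_lapse) idx$le <- take(1L)
  idx
}

# per-draw participant-level component values: list of [draws x P] matrices
participant_component_draws <- function(fit) {
  dat <- fit$prep$data
  idx <- par_layout(dat)
  dr <- fit$draws
  P <- dat$P
  Xt <- t(dat$X)

  lin <- function(b_idx, comp) {
    out <- dr[, b_idx, drop = FALSE] %*% Xt
    if (dat$has_mono) {
      c_i <- match(comp, c("A", "S", "R"))
      zeta1 <- stats::plogis(dr[, idx$r[c_i]])
      cz <- outer(zeta1, dat$vlev, function(z, lv) {
        ifelse(lv == 0, 0, ifelse(lv == 1, z, 1))
      })
      bv <- dr[, idx$bv[c_i]]
      slope <- if (dat$mono_int) {
        bv + outer(dr[, idx$bav[c_i]], dat$xage)
      } else {
        matrix(bv, nrow(dr), P)
      }
      out <- out + slope * cz
    }
    out
  }

  sig <- exp(dr[, idx$logsig, drop = FALSE])
  list(
    A = lin(idx$bA, "A") + sig[, 1] * dr[, idx$zA, drop = FALSE],
    S = lin(idx$bS, "S") + sig[, 2] * dr[, idx$zS, drop = FALSE],
    R = lin(idx$bR, "R") + sig[, 3] * dr[, idx$zR, drop = FALSE],
    log_shape = matrix(dr[, idx$bsh], nrow(dr), P) +
      sig[, 4] * dr[, idx$zsh, drop = FALSE],
    lapse = if (dat$est_lapse) 0.5 * stats::plogis(dr[, idx$le])
            else rep(dat$lapse, nrow(dr))
  )
}

#' Posterior summaries of the fixed effects
#'
#' One row per fixed-effect term (grouped by component: Asym, Start, Rate,
#' PF shape), with the posterior mean, equal-tailed 95% credible interval,
#' and a reliability flag set when the interval excludes zero. Intercepts
#' are always flagged against zero too, matching the conventional table
#' layout; their flag is rarely of scientific interest.
#'
#' @param fit A `pl_fit`.
#' @param prob Credible-interval mass (default 0.95).
#' @return A tibble with `term`, `estimate`, `conf.low`, `conf.high`,
#'   `reliable`.
#' @export
summarize_fixed_effects <- function(fit, prob = 0.95) {
  stopifnot(inherits(fit, "pl_fit"), prob > 0, prob < 1)
  terms <- order_fixed_terms(fit$fixed_terms)
  a <- (1 - prob) / 2
  purrr::map_dfr(terms, function(tm) {
    x <- fit$draws[, tm]
    qs <- unname(stats::quantile(x, c(a, 1 - a)))
    tibble::tibble(term = tm, estimate = mean(x), conf.low = qs[1],
                   conf.high = qs[2],
                   reliable = qs[1] > 0 | qs[2] < 0)
  })
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Broom-style coefficient table for a fitted learning model
#'
#' @param x A `pl_fit`.
#' @param prob Credible-interval mass.
#' @param ... Unused.
#' @export
tidy.pl_fit <- function(x, prob = 0.95, ...) {
  summarize_fixed_effects(x, prob = prob)
}

#' Broom-style one-row model summary
#'
#' @param x A `pl_fit`.
#' @param ... Unused.
#' @export
glance.pl_fit <- function(x, ...) {
  tibble::tibble(
    model = x$spec$model, age = x$spec$age,
    n_participants = nrow(x$prep$participants),
    n_trials = nrow(x$prep$records),
    chains = max(x$chain), draws = nrow(x$draws),
    max_rhat = max(x$diagnostics$rhat, na.rm = TRUE),
    min_ess_bulk = min(x$diagnostics$ess_bulk, na.rm = TRUE),
    divergences = x$divergences,
    accept_rate = x$accept_rate,
    elapsed_s = x$elapsed_s
  )
}

#' Posterior magnitudes of learning
#'
#' For every posterior draw and participant, the difference between ending
#' and starting accuracy at the design-mean SOA
#' (see [learning_magnitude()]), evaluated between trial 1 and the last
#' modelled trial. Participant summaries and pairwise condition contrasts
#' (differences of condition means of participant magnitudes) are returned
#' with equal-tailed 95% intervals.
#'
#' @param fit A `pl_fit`.
#' @param records Optional trials data frame; defaults to the records the
#'   model was fit to (used for the mean SOA and the trial window).
#' @return A list of class `pl_magnitude` with tibbles `participants` and
#'   `contrasts`.
#' @export
posterior_learning_magnitude <- function(fit, records = NULL) {
  stopifnot(inherits(fit, "pl_fit"))
  if (is.null(records)) records <- fit$prep$records
  mean_soa <- mean(records$soa_ms) / 1000
  t_end <- max(records$trial)
  comp <- participant_component_draws(fit)
  shape <- exp(comp$log_shape)
  lapse <- comp$lapse  # per-draw scalar, recycled by column below

  th0 <- threshold_at(1, comp$S, comp$A, comp$R)
  th1 <- threshold_at(t_end, comp$S, comp$A, comp$R)
  # accuracy difference; the lapse shrinks the PF range by (1 - 2*lapse),
  # so compute at zero lapse and rescale (exact identity, column-recycled)
  mag <- pf_probability(mean_soa, th1, shape, 0) -
    pf_probability(mean_soa, th0, shape, 0)
  mag <- mag * (1 - 2 * lapse)

  ids <- fit$prep$participants$participant_id
  cond <- fit$prep$participants$condition
  qs <- function(m) apply(m, 2, stats::quantile, c(0.025, 0.975))
  pq <- qs(mag)
  participants <- tibble::tibble(
    participant_id = ids, condition = cond,
    estimate = colMeans(mag), conf.low = pq[1, ], conf.high = pq[2, ]
  )

  conds <- sort(unique(cond))
  cond_mean <- vapply(conds, function(cn) {
    rowMeans(mag[, cond == cn, drop = FALSE])
  }, numeric(nrow(mag)))
  pairs <- utils::combn(conds, 2, simplify = FALSE)
  contrasts <- purrr::map_dfr(pairs, function(pr) {
    d <- cond_mean[, pr[2]] - cond_mean[, pr[1]]
    tibble::tibble(
      contrast = paste(pr[2], "-", pr[1]),
      estimate = mean(d),
      conf.low = unname(stats::quantile(d, 0.025)),
      conf.high = unname(stats::quantile(d, 0.975))
    )
  })
  structure(list(participants = participants, contrasts = contrasts,
                 mean_soa_s = mean_soa, t_end = t_end),
            class = "pl_magnitude")
}

#' @export
print.pl_magnitude <- function(x, ...) {
  cat("<pl_magnitude> learning magnitude at mean SOA ",
      sprintf("%.1f", 1000 * x$mean_soa_s), " ms, trials 1 to ", x$t_end,
      "\n", sep = "")
  print(x$contrasts)
  invisible(x)
}
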