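#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Group-level learning curves from a fitted model
#'
#' Plots the posterior trajectory of the group-level threshold (the Quick
#' midpoint parameter, i.e., the 75% SOA at zero lapse) over trials for
#' each design cell in the fit, with median line and equal-tailed ribbon.
#' Group-level curves set the random effects to zero.
#'
#' @param object A `pl_fit`.
#' @param prob Ribbon mass (default 0.8).
#' @param n_points Trial grid resolution.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pl_fit <- function(object, prob = 0.8, n_points = 60, ...) {
  dat <- object$prep$data
  idx <- par_layout(dat)
  dr <- object$draws
  parts <- object$prep$participants
  cells <- dplyr::distinct(parts, .data$age_group, .data$condition)
  t_grid <- unique(round(seq(1, max(object$prep$records$trial),
                             length.out = n_points)))
  a <- (1 - prob) / 2

  cell_traj <- purrr::pmap_dfr(cells, function(age_group, condition) {
    # design row for this cell, mirroring prepare_model_data()
    xa <- age_code(age_group)
    xr <- arousal_code(condition)
    xrow <- switch(object$spec$model,
      full = c(1, xa, xr, if (dat$mono_int) xa * xr),
      arousal = c(1, xr),
      valence = c(1, ifelse(condition == "positive", 0.5, -0.5)),
      null = 1
    )
    comp_val <- function(b_idx, c_i) {
      v <- dr[, b_idx, drop = FALSE] %*% xrow
      if (dat$has_mono) {
        lv <- valence_level(condition)
        z1 <- stats::plogis(dr[, idx$r[c_i]])
        cz <- ifelse(lv == 0, 0, ifelse(lv == 1, z1, 1))
        slope <- dr[, idx$bv[c_i]] +
          if (dat$mono_int) dr[, idx$bav[c_i]] * xa else 0
        v <- v + slope * cz
      }
      drop(v)
    }
    A <- comp_val(idx$bA, 1)
    S <- comp_val(idx$bS, 2)
    R <- comp_val(idx$bR, 3)
    purrr::map_dfr(t_grid, function(t) {
      th <- threshold_at(t, S, A, R)
      qs <- unname(stats::quantile(th, c(a, 0.5, 1 - a)))
      tibble::tibble(age_group = age_group, condition = condition,
                     trial = t, lower = qs[1], threshold = qs[2],
                     upper = qs[3])
    })
  })

  ggplot2::ggplot(cell_traj,
                  ggplot2::aes(x = .data$trial, y = 1000 * .data$threshold,
                               color = .data$condition,
                               fill = .data$condition)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = 1000 * .data$lower,
                                      ymax = 1000 * .data$upper),
                         alpha = 0.2, color = NA) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~age_group) +
    ggplot2::labs(x = "trial", y = "threshold SOA (ms, log scale)",
                  title = "Posterior group-level learning curves") +
    ggplot2::theme_minimal()
}

#' Bar chart of base-3 log Bayes factors
#'
#' @param object A `pl_comparisons` tibble.
#' @param ... Unused.
#' @return A ggplot object with the moderate-evidence bounds at -1 and +1.
#' @export
autoplot.pl_comparisons <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$label,
                                       y = .data$log3_bf,
                                       fill = .data$verdict)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = c(-1, 1), linetype = "dashed") +
    ggplot2::labs(x = NULL, y = expression(log[3] ~ "Bayes factor"),
                  title = "Evidence for condition effects vs null") +
    ggplot2::theme_minimal()
}

#' Plot smoothed group accuracies over trials
#'
#' @param smoothed Output of [smooth_accuracy()].
#' @return A ggplot object, one line per condition, faceted by age group.
#' @export
plot_smoothed_accuracy <- function(smoothed) {
  ggplot2::ggplot(smoothed,
                  ggplot2::aes(x = .data$trial, y = .data$accuracy,
                               color = .data$condition)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dotted") +
    ggplot2::facet_wrap(~age_group) +
    ggplot2::labs(x = "trial", y = "proportion correct",
                  title = "Moving-window group accuracy") +
    ggplot2::theme_minimal()
}
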