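#' Plot a cross-correlogram with Poisson limits
#'
#' Bars of partner-call counts per lag bin around the focal calls, with
#' the baseline intensity and its Poisson confidence limits overlaid and
#' the answer window (0, 0.5] s shaded.
#'
#' @param object A `correlogram` from [cross_correlogram()].
#' @param alpha Significance level for the overlaid limits.
#' @param answer_window_s Shaded answer window (s).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.correlogram <- function(object, alpha = 0.05,
                                 answer_window_s = 0.5, ...) {
  lim <- poisson_limits(object, alpha = alpha)
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$bin_center_s, y = .data$count)) +
    ggplot2::annotate("rect", xmin = 0, xmax = answer_window_s,
                      ymin = -Inf, ymax = Inf, alpha = 0.12,
                      fill = "steelblue") +
    ggplot2::geom_col(width = attr(object, "bin_width_s"),
                      fill = "grey30") +
    ggplot2::geom_hline(yintercept = lim$lambda, linetype = 2) +
    ggplot2::geom_hline(yintercept = c(lim$lower, lim$upper),
                        colour = "firebrick") +
    ggplot2::labs(
      x = "lag of partner call relative to focal call (s)",
      y = sprintf("calls per bin (n focal = %d)", attr(object, "n_focal")),
      title = "Cross-correlogram of partner calls",
      subtitle = sprintf("baseline λ = %.2f, %d%% Poisson limits",
                         lim$lambda, round(100 * (1 - alpha)))
    ) +
    ggplot2::theme_minimal()
}

#' Directionality index per pair over days
#'
#' One line per pair; symmetric exchange sits at 0.
#'
#' @param pair_days A pair-day summary tibble (see
#'   [summarise_pair_days()]) with `pair_id`, `experience`, `day`,
#'   `directionality`.
#' @return A ggplot object.
#' @export
plot_directionality <- function(pair_days) {
  ggplot2::ggplot(pair_days,
                  ggplot2::aes(x = .data$day, y = .data$directionality,
                               group = .data$pair_id,
                               colour = .data$experience)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "day", y = "directionality index (x100)",
                  colour = "pair experience") +
    ggplot2::theme_minimal()
}

#' Model diagnostics plots
#'
#' Residuals vs fitted and a residual histogram for an `ap_lmm`.
#'
#' @param x An `ap_lmm` from [fit_lmm()].
#' @return A ggplot object (two panels via facetting).
#' @export
plot_diagnostics <- function(x) {
  d <- lmm_diagnostics(x)
  long <- bind_rows(
    tibble(panel = "residual vs fitted", x = d$fitted, y = d$residual),
    tibble(panel = "residual distribution", x = d$residual, y = NA_real_)
  )
  ggplot2::ggplot() +
    ggplot2::geom_point(
      data = filter(long, .data$panel == "residual vs fitted"),
      ggplot2::aes(x = .data$x, y = .data$y), alpha = 0.6) +
    ggplot2::geom_histogram(
      data = filter(long, .data$panel == "residual distribution"),
      ggplot2::aes(x = .data$x), bins = 20) +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
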