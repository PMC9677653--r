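#' Plot a cohort trace
#'
#' State occupancy over cycles for one strategy.
#'
#' @param object A `cohort_trace`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cohort_trace
#' @export
autoplot.cohort_trace <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$cycle, .data$occupancy,
                                   colour = .data$state)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Cycle (years since initiation)",
                  y = "Fraction of cohort",
                  title = paste0(object$strategy, "-first cohort, start age ",
                                 object$start_age)) +
    ggplot2::theme_minimal()
}

#' Incremental cost-effectiveness plane
#'
#' Per-draw (QALY difference, cost difference) scatter of HD-first versus
#' PD-first, with the willingness-to-pay line.
#'
#' @param object A `psa_result`.
#' @param wtp Willingness-to-pay threshold drawn as a reference line.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot psa_result
#' @export
autoplot.psa_result <- function(object, wtp = 4766, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$delta_qaly, .data$delta_cost)) +
    ggplot2::geom_point(alpha = 0.2, size = 0.6) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3) +
    ggplot2::geom_abline(slope = wtp, intercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "Incremental QALYs (HD-first - PD-first)",
                  y = "Incremental cost (USD)",
                  title = "Incremental cost-effectiveness plane") +
    ggplot2::theme_minimal()
}

#' Cost-effectiveness acceptability curve plot
#'
#' @param object A `ceac_curve`.
#' @param wtp Willingness-to-pay threshold drawn as a reference line.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ceac_curve
#' @export
autoplot.ceac_curve <- function(object, wtp = 4766, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$wtp, .data$prob,
                                       colour = .data$strategy)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = wtp, linetype = "dashed") +
    ggplot2::labs(x = "Willingness to pay (USD per QALY)",
                  y = "Probability cost-effective",
                  title = "Cost-effectiveness acceptability curve") +
    ggplot2::theme_minimal()
}

#' Tornado diagram
#'
#' Ranked one-way sensitivity of the ICER to each parameter's low/high
#' bounds.
#'
#' @param object A `tornado_result`.
#' @param top Number of parameters to show.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot tornado_result
#' @export
autoplot.tornado_result <- function(object, top = 15, ...) {
  df <- utils::head(object[object$defined, ], top)
  df$label <- factor(df$label, levels = rev(df$label))
  base <- attr(object, "base_icer")
  ggplot2::ggplot(df) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$icer_low, xend = .data$icer_high,
                                       y = .data$label, yend = .data$label),
                          linewidth = 4, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = base, linetype = "dashed") +
    ggplot2::labs(x = "ICER (USD per QALY)", y = NULL,
                  title = "One-way sensitivity of the ICER") +
    ggplot2::theme_minimal()
}
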