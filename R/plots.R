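#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot methods for model results
#'
#' `autoplot()` methods render each result type with ggplot2: PSA outcome
#' distributions, the tornado diagram, state occupancy over time, the yearly
#' incremental ROI, and scenario sweeps.
#'
#' @param object a result object.
#' @param ... unused.
#' @return a ggplot.
#' @name autoplot.bia_psa
NULL

#' @param outcome which PSA outcome column to plot.
#' @rdname autoplot.bia_psa
#' @export
autoplot.bia_psa <- function(object, outcome = "roi_disc", ...) {
  df <- object$draws
  s <- object$summaries[object$summaries$outcome == outcome, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[outcome]])) +
    ggplot2::geom_histogram(bins = 40, fill = "steelblue", colour = "white") +
    ggplot2::geom_vline(xintercept = c(s$lo95, s$median, s$hi95),
                        linetype = c("dashed", "solid", "dashed")) +
    ggplot2::labs(x = outcome, y = "draws",
                  title = sprintf("PSA: %s (median %.4g, 95%% CI %.4g-%.4g)",
                                  outcome, s$median, s$lo95, s$hi95)) +
    ggplot2::theme_minimal()
}

#' @param top number of parameters to display.
#' @rdname autoplot.bia_psa
#' @export
autoplot.bia_tornado <- function(object, top = 12, ...) {
  df <- utils::head(tibble::as_tibble(object), top)
  df$parameter <- factor(df$parameter, levels = rev(df$parameter))
  base <- attr(object, "base_value")
  ggplot2::ggplot(df) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$outcome_at_low,
                                       xend = .data$outcome_at_high,
                                       y = .data$parameter, yend = .data$parameter),
                          linewidth = 4, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = base, linetype = "dashed") +
    ggplot2::labs(x = attr(object, "outcome"), y = NULL,
                  title = "One-way sensitivity analysis") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.bia_psa
#' @export
autoplot.bia_trace <- function(object, ...) {
  df <- dplyr::summarise(dplyr::group_by(tibble::as_tibble(object),
                                         .data$cycle, .data$state),
                         count = sum(.data$count), .groups = "drop")
  df$state <- factor(df$state, levels = markov_states())
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cycle, y = .data$count,
                                   fill = .data$state)) +
    ggplot2::geom_area() +
    ggplot2::labs(x = "30-day cycle", y = "expected patients",
                  title = "State occupancy over the time horizon") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.bia_psa
#' @export
autoplot.bia_roi <- function(object, ...) {
  df <- dplyr::filter(object$yearly, .data$year > 0)
  df_long <- tidyr::pivot_longer(
    dplyr::select(df, dplyr::all_of(c("year", "d_cost", "d_revenue", "roi"))),
    -"year", names_to = "stream", values_to = "usd")
  ggplot2::ggplot(df_long, ggplot2::aes(x = factor(.data$year), y = .data$usd,
                                        fill = .data$stream)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "model year", y = "incremental USD",
                  title = "Yearly incremental revenue, cost, and ROI") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.bia_psa
#' @export
autoplot.bia_sweep <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$setting, y = .data$roi_disc)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = unique(df$axis), y = "discounted ROI (USD)",
                  title = "Scenario sweep") +
    ggplot2::theme_minimal()
}
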