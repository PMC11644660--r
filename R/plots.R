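#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an RGB trace
#'
#' @param object An [rgb_trace()].
#' @param ... Unused.
#' @return A ggplot: channel intensity against time.
#' @method autoplot rgb_trace
#' @export
autoplot.rgb_trace <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object), c("r", "g", "b"),
                              names_to = "channel", values_to = "intensity")
  ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$intensity,
                                     colour = .data$channel)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(values = c(r = "#c0392b", g = "#27ae60",
                                            b = "#2980b9")) +
    ggplot2::labs(x = "time (s)", y = "mean intensity", colour = "channel")
}

#' Plot a pulse signal
#'
#' @param object A [pulse_signal()].
#' @param ... Unused.
#' @return A ggplot of the signal over time.
#' @method autoplot pulse_signal
#' @export
autoplot.pulse_signal <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(.data$time, .data$value)) +
    ggplot2::geom_line(colour = "#2c3e50") +
    ggplot2::labs(x = "time (s)", y = "amplitude",
                  title = paste("pulse signal:", attr(object, "method") %||% ""))
}

#' Plot a magnitude spectrum
#'
#' @param object A [magnitude_spectrum()] result.
#' @param band Optional [filter_spec()] shown as a shaded passband.
#' @param ... Unused.
#' @return A ggplot of magnitude against frequency.
#' @method autoplot pulse_spectrum
#' @export
autoplot.pulse_spectrum <- function(object, band = NULL, ...) {
  p <- ggplot2::ggplot(tibble::as_tibble(object),
                       ggplot2::aes(.data$freq, .data$magnitude)) +
    ggplot2::geom_line(colour = "#2c3e50") +
    ggplot2::labs(x = "frequency (Hz)", y = "|X(f)|")
  if (!is.null(band)) {
    p <- p + ggplot2::annotate("rect", xmin = band$low, xmax = band$high,
                               ymin = -Inf, ymax = Inf, alpha = 0.15,
                               fill = "#27ae60")
  }
  p
}

#' Plot feature importances
#'
#' @param importance A [feature_importance()] tibble.
#' @return A horizontal bar chart, most important feature on top.
#' @export
plot_importance <- function(importance) {
  ggplot2::ggplot(importance,
                  ggplot2::aes(.data$importance,
                               stats::reorder(.data$feature, .data$importance))) +
    ggplot2::geom_col(fill = "#2980b9") +
    ggplot2::labs(x = "importance (fraction of total)", y = NULL)
}

#' Plot a partial-dependence curve
#'
#' @param object A [partial_dependence()] result.
#' @param ... Unused.
#' @return A ggplot of mean prediction against the feature value.
#' @method autoplot pulsemodal_pdp
#' @export
autoplot.pulsemodal_pdp <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(.data$value, .data$prediction)) +
    ggplot2::geom_line(colour = "#2c3e50") +
    ggplot2::labs(x = attr(object, "feature"), y = "partial dependence (bpm)")
}

#' Plot an ablation table
#'
#' @param object A `pulsemodal_ablation`.
#' @param metric Which metric to draw.
#' @param ... Unused.
#' @return A bar chart of the chosen metric per method/modality row.
#' @method autoplot pulsemodal_ablation
#' @export
autoplot.pulsemodal_ablation <- function(object, metric = c("mae", "rmse", "mape"),
                                         ...) {
  metric <- match.arg(metric)
  d <- tidy(object)
  d$label <- sprintf("%s %s%s", toupper(d$method),
                     ifelse(d$video, "+video", ""),
                     ifelse(d$physical, "+physical", ""))
  ggplot2::ggplot(d, ggplot2::aes(.data$label, .data[[metric]],
                                  fill = .data$method)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = toupper(metric)) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
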