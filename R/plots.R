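#' Plot a simulated voltage trace
#'
#' @param object A `ca1_trace`.
#' @param from,to Time window to show, ms.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ca1_trace <- function(object, from = NULL, to = NULL, ...) {
  df <- tibble::as_tibble(object)
  if (!is.null(from)) df <- df[df$time >= from, ]
  if (!is.null(to)) df <- df[df$time <= to, ]
  cols <- intersect(c("v_soma", "v_dend"), names(df))
  long <- tidyr::pivot_longer(df[, c("time", cols)], -"time",
                              names_to = "compartment", values_to = "v")
  ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$v,
                                     colour = .data$compartment)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (ms)", y = "membrane potential (mV)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot SS/BS tuning curves
#'
#' @param object A `tuning_curve`.
#' @param ... Unused.
#' @return A ggplot of event rate vs input frequency per event type.
#' @export
autoplot.tuning_curve <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("freq", "rate_ss", "rate_bs")],
    -"freq", names_to = "type", values_to = "rate")
  long$type <- toupper(sub("rate_", "", long$type))
  ggplot2::ggplot(long, ggplot2::aes(.data$freq, .data$rate,
                                     colour = .data$type)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "input frequency (Hz)", y = "event rate (Hz)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot event probability conditioned on the quiet interval
#'
#' @param prob Output of [event_probability_by_interval()].
#' @return A ggplot of P(BS) and P(SS) per interval bin.
#' @export
plot_interval_probability <- function(prob) {
  long <- tidyr::pivot_longer(prob[, c("bin_lo", "p_ss", "p_bs")], -"bin_lo",
                              names_to = "type", values_to = "p")
  long$type <- toupper(sub("p_", "", long$type))
  ggplot2::ggplot(long[!is.na(long$p), ],
                  ggplot2::aes(.data$bin_lo, .data$p, fill = .data$type)) +
    ggplot2::geom_col(position = "dodge", width = 8) +
    ggplot2::labs(x = "preceding quiet interval (ms)",
                  y = "event-type probability", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot per-area burst vs single-spike interval mass
#'
#' @param object An `area_stats` object.
#' @param ... Unused.
#' @return A ggplot of per-cell area masses by event type.
#' @export
autoplot.area_stats <- function(object, ...) {
  long <- tidyr::pivot_longer(object$per_cell, c("mass_ss", "mass_bs"),
                              names_to = "type", values_to = "mass")
  long$type <- toupper(sub("mass_", "", long$type))
  ggplot2::ggplot(long, ggplot2::aes(.data$type, .data$mass)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, size = 1, alpha = 0.6) +
    ggplot2::facet_wrap(~area) +
    ggplot2::labs(x = NULL, y = "interval density mass per cell") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
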