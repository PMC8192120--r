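#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an occupancy trajectory
#'
#' One line per state occupancy against time.
#'
#' @param object An `occupancy_trajectory`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.occupancy_trajectory <- function(object, ...) {
  long <- occupancy_long(object)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$occupancy,
                                     colour = .data$state)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "occupancy") +
    ggplot2::theme_minimal()
}

#' Plot a current trace
#'
#' @param object A `current_trace`.
#' @param ... Unused.
#' @return A ggplot object (current in pA).
#' @export
autoplot.current_trace <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time,
                                       y = .data$current * 1e12)) +
    ggplot2::geom_line(colour = "firebrick") +
    ggplot2::labs(x = "time (s)", y = "current (pA)") +
    ggplot2::theme_minimal()
}

#' Plot a fluorescence-uptake trace
#'
#' @param object A `fluorescence_trace`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fluorescence_trace <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time,
                                       y = .data$fluorescence)) +
    ggplot2::geom_line(colour = "darkorange") +
    ggplot2::labs(x = "time (s)", y = "fluorescence (AU)") +
    ggplot2::theme_minimal()
}

#' Plot a synthetic two-channel recording
#'
#' Stacked current and fluorescence panels sharing the time axis.
#'
#' @param object A `recording`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.recording <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              c("current", "fluorescence"),
                              names_to = "channel", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~channel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a protocol result
#'
#' Chooses the x axis from the columns present (`voltage`,
#' `concentration` or `wash_time`) and plots the normalized readouts.
#'
#' @param object A `protocol_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.protocol_result <- function(object, ...) {
  df <- tibble::as_tibble(object)
  xcol <- intersect(c("voltage", "concentration", "wash_time"), names(df))[1]
  ycols <- intersect(c("uptake_slope_norm", "peak_norm", "steady_norm",
                       "recovery"), names(df))
  if (length(ycols) == 0) ycols <- setdiff(names(df), xcol)[1]
  long <- tidyr::pivot_longer(df[, c(xcol, ycols)], -1,
                              names_to = "readout", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data[[xcol]], y = .data$value,
                                     colour = .data$readout)) +
    ggplot2::geom_point() + ggplot2::geom_line() +
    ggplot2::labs(x = xcol, y = "normalized value") +
    ggplot2::theme_minimal()
}

#' Plot a free-energy profile
#'
#' Cumulative Gibbs free energy along the path, in kJ/mol.
#'
#' @param object An `energy_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.energy_profile <- function(object, ...) {
  df <- tibble::tibble(step = c(0, seq_len(nrow(object))),
                       state = c(object$from[1], object$to),
                       cumulative = c(0, object$cumulative) / 1000)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$step, y = .data$cumulative)) +
    ggplot2::geom_step() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = df$step, labels = df$state) +
    ggplot2::labs(x = NULL, y = expression(Delta * G ~ "(kJ/mol)")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @importFrom rlang .data
NULL
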