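# ggplot2 display helpers for the main result types.

#' Plot a melting curve with detected transitions
#'
#' @param curves Curve table (`temperature_C`, `absorbance`, `direction`).
#' @param transitions Optional [detect_transitions()] / [analyze_melt()]
#'   transition table; detected temperatures are drawn as dashed verticals.
#' @return A ggplot object.
#' @export
plot_melt_curve <- function(curves, transitions = NULL) {
  p <- ggplot2::ggplot(curves,
                       ggplot2::aes(x = .data$temperature_C,
                                    y = .data$absorbance,
                                    colour = .data$direction)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Temperature (°C)", y = "A295 (AU)",
                  colour = NULL)
  if (!is.null(transitions) && nrow(transitions) > 0) {
    p <- p + ggplot2::geom_vline(
      data = transitions,
      ggplot2::aes(xintercept = .data$temperature),
      linetype = "dashed", colour = "grey40")
  }
  p
}

#' Plot a thermal difference spectrum
#'
#' @param tds A normalized TDS from [compute_tds()].
#' @return A ggplot object annotated with the [classify_tds()] call.
#' @export
plot_tds <- function(tds) {
  label <- classify_tds(tds)
  ggplot2::ggplot(tds, ggplot2::aes(x = .data$wavelength_nm,
                                    y = .data$delta_abs)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Wavelength (nm)",
                  y = expression(Delta * "A (normalized)"),
                  subtitle = paste("classified as:", label))
}

#' @describeIn fit_titration Plot the titration data, fitted sigmoid and
#'   transitional pH.
#' @param object A `titration_fit`.
#' @param ... Unused.
#' @method autoplot titration_fit
#' @export
autoplot.titration_fit <- function(object, ...) {
  grid <- tibble(ph = seq(min(object$data$ph), max(object$data$ph),
                          length.out = 200))
  grid$fit <- predict(object, grid)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$ph, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$fit)) +
    ggplot2::geom_vline(xintercept = object$ph_t, linetype = "dashed") +
    ggplot2::labs(x = "pH", y = "Ellipticity at 288 nm (mdeg)",
                  subtitle = sprintf("pHT = %.2f", object$ph_t))
}

#' Plot hit counts versus the maximum loop length
#'
#' @param counts Output of [count_vs_loopmax()].
#' @return A ggplot object.
#' @export
plot_loopmax_scaling <- function(counts) {
  ggplot2::ggplot(counts, ggplot2::aes(x = .data$loop_max,
                                       y = .data$n_hits)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Maximum loop length (nt)", y = "Hits")
}
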