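#' Plot stress-strain curves
#'
#' @param curves A tibble with columns `strain`, `stress_pa`, `orientation`
#'   (and optionally `specimen`), e.g. from [predict_curve()],
#'   [generate_curves()] or [engineering_curve()].
#' @param ... Unused.
#' @return A ggplot, stress in kPa against engineering strain, one panel per
#'   orientation.
#' @examples
#' plot_curves(predict_curve(colorectal_params(), seq(0, 0.2, 0.01), "circ"))
#' @export
plot_curves <- function(curves, ...) {
  grp <- if ("specimen" %in% names(curves)) {
    ggplot2::aes(group = .data$specimen)
  } else {
    NULL
  }
  p <- ggplot2::ggplot(
    curves,
    ggplot2::aes(x = .data$strain, y = .data$stress_pa / 1e3)
  ) +
    ggplot2::geom_line(alpha = 0.6, mapping = grp) +
    ggplot2::facet_wrap(~orientation, scales = "free_y") +
    ggplot2::labs(x = "engineering strain", y = "engineering stress (kPa)") +
    ggplot2::theme_minimal()
  p
}

#' Plot a load record
#'
#' @param object A `load_record` tibble.
#' @param ... Unused.
#' @return A ggplot of force and displacement against time.
#' @method autoplot load_record
#' @export
autoplot.load_record <- function(object, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(object), c("force_n", "displacement_mm"),
    names_to = "channel", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_s, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~channel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL) +
    ggplot2::theme_minimal()
}
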