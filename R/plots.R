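#' Plot a perfusion trace
#'
#' Pressure and flow panels against time, the standard way step responses
#' of perfusion systems are displayed.
#'
#' @param object A `perfusion_trace` from [simulate_perfusion()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.perfusion_trace <- function(object, ...) {
  df <- tidyr::pivot_longer(
    as_tibble(object)[, c("time_min", "p_s", "p_e", "f_s", "f_e")],
    -"time_min", names_to = "series", values_to = "value"
  )
  df$panel <- ifelse(df$series %in% c("p_s", "p_e"),
                     "pressure (mmHg)", "flow (ul/min)")
  ggplot2::ggplot(df, ggplot2::aes(.data$time_min, .data$value,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (min)", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a facility experiment
#'
#' Steady-state eye inflow against eye pressure with the fitted
#' regression line whose slope is the outflow facility estimate.
#'
#' @param object A `facility_fit` from [run_experiment()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.facility_fit <- function(object, ...) {
  st <- object$steps[object$steps$converged, , drop = FALSE]
  ggplot2::ggplot(st, ggplot2::aes(.data$steady_p_e, .data$steady_f_e)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_abline(slope = object$facility,
                         intercept = object$intercept, linetype = 2) +
    ggplot2::labs(
      x = "steady-state eye pressure (mmHg)",
      y = "steady-state eye inflow (ul/min)",
      title = sprintf("facility %.1f nl/min/mmHg, R = %.4f",
                      1000 * object$facility, object$pearson_r)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a gain sweep
#'
#' Settling time against feedback gain on a log axis.
#'
#' @param sweep Output of [gain_sweep()] (several sweeps may be bound
#'   together).
#' @return A ggplot object.
#' @export
plot_gain_sweep <- function(sweep) {
  ggplot2::ggplot(sweep, ggplot2::aes(.data$gain, .data$settling_min,
                                      colour = .data$mode)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "feedback gain (ul/min/mmHg)",
                  y = "settling time (min)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
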