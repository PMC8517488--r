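#' Plot a basis waveform
#'
#' @param object A [basis_waveform()].
#' @param duration_ms Plot horizon (ms); defaults to five times the
#'   slowest decay constant.
#' @param dt Sample step (ms).
#' @param ... Ignored.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.basis_waveform <- function(object, duration_ms = NULL, dt = 0.1,
                                    ...) {
  duration_ms <- duration_ms %||% (5 * max(object$tc2, object$tc3))
  tt <- seq(0, duration_ms, by = dt)
  df <- tibble::tibble(time_ms = tt, value = evaluate_basis(object, tt))
  ggplot2::ggplot(df, ggplot2::aes(.data$time_ms, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "time since event (ms)", y = "normalized response",
      title = sprintf("Tc = (%.3g, %.3g, %.3g) ms, w = %.3g",
                      object$tc1, object$tc2, object$tc3, object$w)
    )
}

#' Plot a validation report
#'
#' NRMSE (and van Rossum distance, when present) against input rate, one
#' line per synapse model, averaged over seeds.
#'
#' @param object A report from [run_validation()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.validation_report <- function(object, ...) {
  df <- tibble::as_tibble(object)
  long <- df |>
    dplyr::select(dplyr::any_of(c("model", "rate_hz", "nrmse", "vrd"))) |>
    tidyr::pivot_longer(dplyr::any_of(c("nrmse", "vrd")),
                        names_to = "metric", values_to = "value") |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::group_by(.data$model, .data$rate_hz, .data$metric) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop")
  ggplot2::ggplot(long, ggplot2::aes(.data$rate_hz, .data$value,
                                     colour = .data$model)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "input rate (Hz)", y = "mean over seeds")
}

#' Overlay output traces from several synapse models
#'
#' @param traces Named list of tibbles with `time_ms`, `value`.
#' @return A ggplot object.
#' @export
plot_trace_comparison <- function(traces) {
  df <- dplyr::bind_rows(traces, .id = "model")
  ggplot2::ggplot(df, ggplot2::aes(.data$time_ms, .data$value,
                                   colour = .data$model)) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::labs(x = "time (ms)", y = "output")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
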