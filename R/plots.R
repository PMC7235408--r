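#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an LFP recording
#'
#' @param object An [lfp_recording()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.lfp_recording <- function(object, ...) {
  as_tibble(object) |>
    ggplot2::ggplot(ggplot2::aes(.data$time, .data$amplitude)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(
      x = "time (s)", y = "amplitude (µV)", title = object$label
    ) +
    ggplot2::theme_minimal()
}

#' Plot a time-frequency power map
#'
#' Log-power spectrogram of an [stft_power()] map, cropped to `max_freq`.
#'
#' @param object An [stft_power()] object.
#' @param max_freq Upper frequency to display (Hz), default 50.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.stft_power <- function(object, max_freq = 50, ...) {
  as_tibble(object) |>
    dplyr::filter(.data$freq <= max_freq) |>
    ggplot2::ggplot(ggplot2::aes(.data$time, .data$freq, fill = log10(.data$power + 1e-12))) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "log10 power") +
    ggplot2::labs(x = "time (s)", y = "frequency (Hz)") +
    ggplot2::theme_minimal()
}

#' Plot a controller run
#'
#' Trigger raster over the per-iteration (phase mode) or per-window (seizure
#' mode) decision trace.
#'
#' @param object A `cltus_run` report.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.cltus_run <- function(object, ...) {
  if (object$mode == "seizure") {
    p <- ggplot2::ggplot(object$log, ggplot2::aes(.data$window_end)) +
      ggplot2::geom_line(ggplot2::aes(y = .data$h_ratio, colour = "H ratio")) +
      ggplot2::geom_line(ggplot2::aes(y = .data$cl_ratio, colour = "CL ratio")) +
      ggplot2::geom_hline(yintercept = c(
        object$config[["detect.h_mult"]], object$config[["detect.cl_mult"]]
      ), linetype = 3) +
      ggplot2::labs(x = "time (s)", y = "ratio to baseline", colour = NULL)
  } else {
    p <- ggplot2::ggplot(object$log, ggplot2::aes(.data$t_buffer_end, .data$A_p)) +
      ggplot2::geom_point(size = 0.4, na.rm = TRUE) +
      ggplot2::labs(x = "time (s)", y = "estimated theta period A_p (s)")
  }
  if (nrow(object$triggers)) {
    p <- p + ggplot2::geom_vline(
      xintercept = object$triggers$time_s,
      colour = "red", alpha = 0.5, linetype = 2
    )
  }
  p + ggplot2::theme_minimal()
}

#' Plot paired experiment outcomes
#'
#' Per-subject mean seizure latency and duration, closed-loop vs sham, with
#' pairing lines.
#'
#' @param object A [run_experiment()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.cltus_experiment <- function(object, ...) {
  tidyr::pivot_longer(object,
    cols = c("mean_latency_s", "mean_duration_s"),
    names_to = "outcome", values_to = "seconds"
  ) |>
    dplyr::mutate(outcome = dplyr::recode(.data$outcome,
      mean_latency_s = "latency", mean_duration_s = "duration"
    )) |>
    ggplot2::ggplot(ggplot2::aes(.data$arm, .data$seconds)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$seed), alpha = 0.4) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~outcome, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "seconds") +
    ggplot2::theme_minimal()
}
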