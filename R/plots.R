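#' Plot per-frequency SNR curves of an evaluation report
#'
#' One curve per method over the carrier-frequency grid (log axis), the
#' standard way the benchmark comparison is visualized.
#'
#' @param object An `eval_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eval_report <- function(object, ...) {
  ggplot2::ggplot(object$per_freq_snr,
                  ggplot2::aes(x = .data$carrier_freq, y = .data$snr_db,
                               colour = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_x_log10(labels = function(x) sprintf("%g kHz", x / 1e3)) +
    ggplot2::labs(x = "carrier frequency", y = "SNR (dB)",
                  colour = "method",
                  title = "Per-frequency SNR after each processing method") +
    ggplot2::theme_minimal()
}

#' Plot the training history of a fitted denoiser
#' @param object A `trained_denoiser`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.trained_denoiser <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history, c("train_mse", "val_mse"),
                           names_to = "series", values_to = "mse")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$mse,
                                  colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "epoch", y = "standardized MSE",
                  title = sprintf("Training history (%s preset, seed %d)",
                                  object$config$name, object$seed)) +
    ggplot2::theme_minimal()
}

#' Plot a sweep of denoiser configurations
#' @param object A `config_sweep`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.config_sweep <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$config, y = .data$snr_improvement_db)) +
    ggplot2::geom_point(ggplot2::aes(colour = factor(.data$seed)), size = 2) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.3,
                          linewidth = 0.3) +
    ggplot2::labs(x = "configuration", y = "SNR improvement (dB)",
                  colour = "seed",
                  title = "Held-out SNR improvement by filter-count configuration") +
    ggplot2::theme_minimal()
}

#' Plot one benchmark window
#'
#' Clean and noisy traces of a single window, in microampere.
#' @param dataset A `sinw_benchmark`.
#' @param window_id Window id.
#' @param denoised Optional denoised trace to overlay.
#' @return A ggplot object.
#' @export
plot_window <- function(dataset, window_id, denoised = NULL) {
  i <- match(window_id, dataset$window_id)
  if (is.na(i)) abort(sprintf("window_id %s not found", window_id))
  fs <- attr(dataset, "fs")
  T <- attr(dataset, "T")
  df <- tibble::tibble(
    t_us = (seq_len(T) - 1) / fs * 1e6,
    clean = dataset$clean[[i]] * 1e6,
    noisy = dataset$noisy[[i]] * 1e6
  )
  if (!is.null(denoised)) df$denoised <- denoised * 1e6
  long <- tidyr::pivot_longer(df, -"t_us", names_to = "trace", values_to = "isd_uA")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t_us, y = .data$isd_uA,
                                     colour = .data$trace)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (µs)", y = "Isd (µA)",
                  title = sprintf("window %d: %s at %.3g kHz", window_id,
                                  dataset$analyte[i], dataset$carrier_freq[i] / 1e3)) +
    ggplot2::theme_minimal()
}
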