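#' Clean-referenced signal-to-noise ratio (dB)
#'
#' `10 * log10(sum(clean^2) / sum((estimate - clean)^2))`. Simulation provides
#' the noise-free reference, so SNR is always measured against the stored
#' clean trace. A zero residual returns the `Inf` sentinel.
#'
#' @param clean Clean reference vector (nonzero power).
#' @param estimate Estimate of the same length.
#' @return SNR in dB.
#' @examples
#' snr_db(sin(1:100), sin(1:100) + rnorm(100, sd = 0.01))
#' @export
snr_db <- function(clean, estimate) {
  if (length(clean) != length(estimate)) abort("`clean` and `estimate` lengths differ")
  ps <- sum(clean^2)
  if (ps == 0) abort("`clean` has zero power; SNR undefined")
  pn <- sum((estimate - clean)^2)
  if (pn == 0) return(Inf)
  10 * log10(ps / pn)
}

#' Fraction of noise power removed by a denoiser
#'
#' `1 - sum((denoised - clean)^2) / sum((noisy - clean)^2)`. Equals 1 for
#' perfect reconstruction and 0 when the denoiser returns its input; negative
#' values mean noise was added.
#'
#' @param clean,noisy,denoised Equal-length vectors.
#' @return Fraction in `(-Inf, 1]`.
#' @export
noise_reduction_fraction <- function(clean, noisy, denoised) {
  if (length(unique(c(length(clean), length(noisy), length(denoised)))) != 1) {
    abort("inputs must have equal length")
  }
  p_in <- sum((noisy - clean)^2)
  if (p_in == 0) abort("input noise power is zero; fraction undefined")
  1 - sum((denoised - clean)^2) / p_in
}

#' SNR improvement (dB) of a denoiser over its input
#'
#' `snr_db(clean, denoised) - snr_db(clean, noisy)`; related to
#' [noise_reduction_fraction()] by the exact identity
#' `improvement = -10 * log10(1 - fraction)`.
#'
#' @inheritParams noise_reduction_fraction
#' @return Improvement in dB.
#' @export
snr_improvement_db <- function(clean, noisy, denoised) {
  snr_db(clean, denoised) - snr_db(clean, noisy)
}

#' Threshold-rule virus call for one window
#'
#' The detection statistic is the envelope mean current of the estimated
#' trace (its sample mean, since the excitation tone is a small zero-mean
#' ripple on the binding-set level). The virus is called present when the
#' statistic strictly exceeds the threshold (default 11 uA).
#'
#' @param estimate Trace in ampere.
#' @param threshold Detection threshold (A).
#' @return `"virus_present"` or `"virus_absent"`.
#' @examples
#' detect_virus(rep(12e-6, 100))
#' @export
detect_virus <- function(estimate, threshold = 11e-6) {
  if (mean(estimate) > threshold) "virus_present" else "virus_absent"
}

confusion_metrics <- function(truth, call) {
  pos <- truth == "virus_present"
  called <- call == "virus_present"
  tp <- sum(pos & called); fn <- sum(pos & !called)
  tn <- sum(!pos & !called); fp <- sum(!pos & called)
  tibble::tibble(
    tp = tp, fp = fp, tn = tn, fn = fn,
    accuracy = (tp + tn) / (tp + tn + fp + fn),
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    cross_reactivity_rate = if (tn + fp > 0) fp / (tn + fp) else NA_real_
  )
}

method_metrics <- function(ds, norm, threshold) {
  snr_before <- purrr::map2_dbl(ds$clean, ds$noisy, snr_db)
  snr_after <- purrr::map2_dbl(ds$clean, ds$denoised, snr_db)
  p_in <- purrr::map2_dbl(ds$clean, ds$noisy, ~ sum((.y - .x)^2))
  p_out <- purrr::map2_dbl(ds$clean, ds$denoised, ~ sum((.y - .x)^2))
  mse_std <- purrr::map2_dbl(ds$clean, ds$denoised,
                             ~ mean(((.y - .x) / norm[["scale"]])^2))
  calls <- purrr::map_chr(ds$denoised, detect_virus, threshold = threshold)
  conf <- confusion_metrics(ds$label, calls)
  list(
    per_window = tibble::tibble(
      window_id = ds$window_id, carrier_freq = ds$carrier_freq,
      snr_before = snr_before, snr_after = snr_after,
      improvement = snr_after - snr_before,
      nrf = 1 - p_out / p_in, mse = mse_std, call = calls
    ),
    summary = tibble::tibble(
      snr_improvement_db = mean(snr_after - snr_before),
      noise_reduction_fraction = mean(1 - p_out / p_in),
      amplitude_reduction_fraction = mean(1 - sqrt(p_out / p_in)),
      mse = mean(mse_std),
      conf
    )
  )
}

#' Evaluate denoising methods on a benchmark split
#'
#' Runs every requested method over the chosen split and assembles the full
#' measurement protocol: per-carrier mean SNR curves, mean SNR improvement,
#' noise-power reduction fraction (and its amplitude-domain variant),
#' standardized MSE, and threshold-rule detection metrics (accuracy,
#' sensitivity, specificity and cross-reactivity, i.e. the fraction of
#' non-target windows called present). A per-class mean response block
#' (fractional impedance change per analyte class) is reported alongside.
#'
#' @param dataset A `sinw_benchmark`.
#' @param methods Character vector of methods (see [apply_method()]).
#' @param model Trained denoiser used for the `"cnn"` method.
#' @param split Which split to evaluate (default `"test"`).
#' @param threshold Detection threshold (A).
#' @param norm Standardization constants (named `center`, `scale`); defaults
#'   to the model's stored constants, else to train-split statistics.
#' @return An object of class `eval_report`: a list with `summary`,
#'   `per_freq_snr`, `per_window`, `class_response`, `n_windows`, `threshold`.
#' @export
evaluate_methods <- function(dataset,
                             methods = c("baseline", "moving_average",
                                         "low_pass", "preamp_only", "cnn"),
                             model = NULL, split = "test",
                             threshold = 11e-6, norm = NULL) {
  ds <- benchmark_split(dataset, split)
  if (is.null(norm)) {
    norm <- if (!is.null(model)) model$norm else benchmark_norm(dataset)
  }
  known <- c("baseline", "moving_average", "low_pass", "preamp_only", "cnn",
             "oracle", "identity")
  if (any(!methods %in% known)) {
    abort(sprintf("unknown method(s): %s",
                  paste(setdiff(methods, known), collapse = ", ")))
  }
  res <- purrr::map(methods, function(m) {
    dd <- apply_method(ds, m, model = model)
    method_metrics(dd, norm, threshold)
  })
  names(res) <- methods

  summary <- dplyr::bind_rows(purrr::map(res, "summary"), .id = "method")
  per_window <- dplyr::bind_rows(purrr::map(res, "per_window"), .id = "method")
  per_freq <- dplyr::summarise(
    dplyr::group_by(per_window, .data$method, .data$carrier_freq),
    snr_db = mean(.data$snr_after), .groups = "drop"
  )
  class_response <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(ds), .data$analyte),
    mean_impedance_change = mean(impedance_change_of(.data$analyte[1], .data$occupancy)),
    mean_isd_uA = mean(.data$isd) * 1e6,
    n = dplyr::n(), .groups = "drop"
  )
  structure(
    list(summary = summary, per_freq_snr = per_freq, per_window = per_window,
         class_response = class_response, n_windows = nrow(ds),
         threshold = threshold, norm = norm),
    class = "eval_report"
  )
}

impedance_change_of <- function(analyte, occupancy) {
  cls <- analyte_class(analyte)
  pmin(pmax(cls$response_coefficient * occupancy, 0), 1)
}

# Train-split standardization constants of a benchmark.
benchmark_norm <- function(dataset) {
  tr <- unlist(dataset$noisy[dataset$split == "train"], use.names = FALSE)
  c(center = mean(tr), scale = sd(tr))
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %d windows, detection threshold %.3g uA\n",
              x$n_windows, x$threshold * 1e6))
  print(x$summary, width = Inf)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
tidy.eval_report <- function(x, ...) x$summary

#' @importFrom generics glance
#' @export
glance.eval_report <- function(x, ...) {
  best <- x$summary[which.max(x$summary$snr_improvement_db), ]
  tibble::tibble(n_windows = x$n_windows, n_methods = nrow(x$summary),
                 best_method = best$method,
                 best_snr_improvement_db = best$snr_improvement_db)
}

#' Write an evaluation report to disk
#'
#' Emits `report.json` (full summary, per-frequency curves, class response and
#' confusion counts), `per_freq_snr.csv` (long format: method, freq_hz,
#' snr_db) and `confusion.csv`.
#'
#' @param report An `eval_report`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_eval_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  per_freq <- dplyr::rename(report$per_freq_snr, freq_hz = "carrier_freq")
  write.csv(per_freq, file.path(dir, "per_freq_snr.csv"), row.names = FALSE)
  conf <- report$summary[, c("method", "tp", "fp", "tn", "fn", "accuracy",
                             "sensitivity", "specificity", "cross_reactivity_rate")]
  write.csv(conf, file.path(dir, "confusion.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(summary = report$summary, per_freq_snr = per_freq,
         class_response = report$class_response,
         n_windows = report$n_windows, threshold_A = report$threshold),
    file.path(dir, "report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(dir)
}
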