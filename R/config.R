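#' Default run configuration
#'
#' Nested configuration driving the end-to-end study: generator settings,
#' classical-filter settings, model/training hyperparameters, quantization,
#' evaluation options and seeds. Serializes losslessly to YAML.
#'
#' @return A list of class `run_config`.
#' @export
default_run_config <- function() {
  structure(list(
    generator = list(
      n_train = 2000L, n_val = 500L, n_test = 500L,
      T = 1024L, fs = 15e6, master_seed = 42L,
      n_freqs = 20L, band = c(6e3, 6e6),
      modulation_depth = 1e-4, snr_db_band = c(46, 56), occupancy_cv = 0.02,
      circuit = list(Rs = 1e3, Cs = 1e-9, Rp = 1e4, Cp = 1e-10,
                     topology = "series_rc_parallel_rc"),
      drive = list(Vds = 0.1, G0 = 1e-4, transduction_gain = 0.25 / 0.92),
      amplifier = list(gain = 100, input_referred_noise_sigma = 2e-9,
                       post_gain_noise_sigma = 0)
    ),
    filters = list(ma_window = 5L, lp_order = 4L, lp_cutoff_factor = 2.5,
                   lp_cutoff_min = 1.5e5),
    model = list(preset = "balanced", output_activation = "linear"),
    training = list(epochs = 55L, batch_size = 32L, lr = 1e-2,
                    patience = 10L, lr_patience = 4L, lr_factor = 0.5,
                    min_lr = 1e-5, warmup_epochs = 2L, kappa = 64,
                    lr_scale_power = 0.5, clip_norm = 0.05,
                    swa_start_frac = 0.5, schedule = "plateau", seeds = c(1L, 2L, 3L)),
    quantization = list(total_bits = 32L, frac_bits = 24L,
                        rounding = "nearest", saturating = TRUE),
    evaluation = list(threshold_uA = 11,
                      methods = c("baseline", "moving_average", "low_pass",
                                  "preamp_only", "cnn")),
    sweep = list(configs = c("low", "balanced", "high"), seeds = c(1L, 2L)),
    output_dir = "sinwfet-run"
  ), class = "run_config")
}

check_keys <- function(value, reference, path = "") {
  if (!is.list(value) || !is.list(reference)) return(invisible())
  unknown <- setdiff(names(value), names(reference))
  if (length(unknown)) {
    abort(sprintf("unknown configuration key(s): %s",
                  paste0(path, unknown, collapse = ", ")))
  }
  for (k in names(value)) check_keys(value[[k]], reference[[k]], paste0(path, k, "."))
}

#' Read / write a run configuration (YAML)
#'
#' Values omitted from the file keep their defaults; keys not present in
#' [default_run_config()] are rejected.
#'
#' @param path YAML file path.
#' @param config A `run_config` (for writing).
#' @return A validated `run_config` (read) or `path` (write).
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  ref <- default_run_config()
  check_keys(user, ref)
  out <- modifyList(ref, user)
  class(out) <- "run_config"
  out
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Build the benchmark described by a run configuration
#' @param config A `run_config`.
#' @return A `sinw_benchmark`.
#' @export
benchmark_from_config <- function(config = default_run_config()) {
  g <- config$generator
  make_benchmark(
    n_train = g$n_train, n_val = g$n_val, n_test = g$n_test,
    freq_grid = default_freq_grid(g$n_freqs, g$band),
    T = g$T, fs = g$fs, master_seed = g$master_seed,
    circuit = do.call(impedance_model, g$circuit),
    drive = do.call(drive_params, g$drive),
    amp = do.call(amplifier_model, g$amplifier),
    modulation_depth = g$modulation_depth, snr_db_band = g$snr_db_band,
    occupancy_cv = g$occupancy_cv
  )
}
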