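# Clean source-drain current trace: a binding-set DC level carrying a small
# excitation tone whose amplitude is attenuated at high frequency, where the
# parallel interface capacitance shunts the excitation (|Z| falls with f).
clean_trace <- function(isd, carrier_freq, T, fs, circuit,
                        modulation_depth = 1e-4, ref_freq = 6e3) {
  att <- Mod(impedance(circuit, carrier_freq)) / Mod(impedance(circuit, ref_freq))
  t <- (seq_len(T) - 1) / fs
  isd * (1 + modulation_depth * att * sin(2 * pi * carrier_freq * t))
}

# Zero-mean band-limited drift, scaled to an exact RMS.
drift_component <- function(T, fs, drift_amp, drift_cutoff) {
  e <- rnorm(T)
  if (drift_amp == 0) return(numeric(T))
  bf <- signal::butter(2, min(drift_cutoff / (fs / 2), 0.99))
  d <- signal::filtfilt(bf, e)
  d <- d - mean(d)
  d * (drift_amp / sqrt(mean(d^2)))
}

# Slow AR(1) phase wander scaled to an exact RMS (rad).
phase_jitter_component <- function(T, rms) {
  e <- rnorm(T)
  if (rms == 0) return(numeric(T))
  j <- as.numeric(stats::filter(e, 0.995, method = "recursive"))
  j * (rms / sqrt(mean(j^2)))
}

# Sparse exponential transients with an expected-power budget of burst_amp^2.
burst_component <- function(T, fs, burst_rate, burst_amp, burst_decay) {
  n <- rpois(1, burst_rate * T / fs)
  if (burst_amp == 0 || burst_rate == 0) return(numeric(T))
  out <- numeric(T)
  if (n == 0) return(out)
  starts <- sample.int(T, n, replace = TRUE)
  signs <- sample(c(-1, 1), n, replace = TRUE)
  len <- min(T, ceiling(5 * burst_decay))
  shape <- exp(-(seq_len(len) - 1) / burst_decay)
  s2 <- sum(shape^2)
  a <- burst_amp * sqrt(T / (burst_rate * T / fs * s2))
  for (k in seq_len(n)) {
    idx <- starts[k]:min(T, starts[k] + len - 1)
    out[idx] <- out[idx] + signs[k] * a * shape[seq_along(idx)]
  }
  out
}

# All stochastic pieces of one window, drawn in a fixed order from one seed.
window_components <- function(cls, noise, amp, carrier_freq, T, fs, seed,
                              circuit, drive, modulation_depth, ref_freq,
                              occupancy_cv) {
  set.seed(seed)
  jit <- rnorm(1)
  occupancy <- cls$equilibrium_occupancy * (1 + occupancy_cv * jit)
  occupancy <- min(max(occupancy, 0), 1)
  impedance_change <- min(max(cls$response_coefficient * occupancy, 0), 1)
  isd <- isd_from_state(impedance_change, drive)
  clean <- clean_trace(isd, carrier_freq, T, fs, circuit, modulation_depth, ref_freq)

  white <- rnorm(T) * noise$white_sigma
  drift <- drift_component(T, fs, noise$drift_amp, noise$drift_cutoff)
  t <- (seq_len(T) - 1) / fs
  tones <- numeric(T)
  for (i in seq_len(nrow(noise$interference_tones))) {
    tone <- noise$interference_tones[i, ]
    phi0 <- runif(1, 0, 2 * pi)
    jitter <- phase_jitter_component(T, tone$phase_jitter)
    tones <- tones + tone$amplitude * sin(2 * pi * tone$freq * t + phi0 + jitter)
  }
  bursts <- burst_component(T, fs, noise$burst_rate, noise$burst_amp, noise$burst_decay)
  mult <- noise$nonlinear_mix * clean * rnorm(T)
  env <- rnorm(T) * amp$input_referred_noise_sigma
  post <- rnorm(T) * amp$post_gain_noise_sigma

  list(clean = clean, occupancy = occupancy, impedance_change = impedance_change,
       isd = isd, white = white, drift = drift, tones = tones, bursts = bursts,
       mult = mult, env = env, post = post)
}

#' Synthesize one benchmark signal window
#'
#' Generates a clean/noisy pair of source-drain current traces. The clean
#' trace is the binding-modulated current level carrying a sinusoidal
#' excitation at `carrier_freq`, attenuated through the equivalent-circuit
#' impedance; the noisy trace adds the amplifier's input-referred noise and
#' the structured acquisition noise:
#' `noisy = gain * (clean + input_noise) + acquisition_noise` rescaled back to
#' current units. In the raw (benchmark) pathway the gain stage is bypassed
#' (`amplified = FALSE`), so the acquisition noise dominates; re-synthesizing
#' the same seed with `amplified = TRUE` yields the preamplifier pathway in
#' which acquisition noise is suppressed by the gain.
#'
#' @param circuit [impedance_model()].
#' @param cls Analyte class (name or one-row tibble, see [analyte_class()]).
#' @param noise [noise_model()]; use [calibrated_noise_model()] for benchmark
#'   windows.
#' @param amp [amplifier_model()].
#' @param carrier_freq Excitation frequency (Hz), must be below `fs / 2`.
#' @param T Window length in samples (positive integer).
#' @param fs Sampling rate (Hz).
#' @param seed Integer seed; identical seeds give bitwise-identical windows.
#' @param amplified Use the amplified (preamplifier) pathway.
#' @param drive [drive_params()].
#' @param modulation_depth Excitation tone relative amplitude at `ref_freq`.
#' @param ref_freq Reference frequency for the carrier attenuation (Hz).
#' @param occupancy_cv Window-to-window coefficient of variation of receptor
#'   occupancy (receptor-density variability).
#'
#' @return A one-row tibble (class `sinw_window`) with columns `analyte`,
#'   `label`, `carrier_freq`, `occupancy`, `isd`, `seed` and list columns
#'   `clean`, `noisy`; attributes `fs` and `T`.
#' @examples
#' w <- synthesize_window(carrier_freq = 1e5, seed = 7)
#' @export
synthesize_window <- function(circuit = impedance_model(),
                              cls = "blank",
                              noise = calibrated_noise_model(carrier_freq, fs = fs, T = T,
                                                             circuit = circuit, drive = drive,
                                                             modulation_depth = modulation_depth),
                              amp = amplifier_model(),
                              carrier_freq, T = 1024, fs = 15e6, seed = 1,
                              amplified = FALSE,
                              drive = drive_params(),
                              modulation_depth = 1e-4, ref_freq = 6e3,
                              occupancy_cv = 0.02) {
  if (is.character(cls)) cls <- analyte_class(cls)
  if (length(T) != 1 || T < 1 || T != round(T)) abort("`T` must be a positive integer")
  if (carrier_freq >= fs / 2) {
    abort(sprintf("carrier_freq (%.3g Hz) violates Nyquist for fs = %.3g Hz", carrier_freq, fs))
  }
  comp <- window_components(cls, noise, amp, carrier_freq, T, fs, seed,
                            circuit, drive, modulation_depth, ref_freq, occupancy_cv)
  acquisition <- comp$white + comp$drift + comp$tones + comp$bursts + comp$mult + comp$post
  noisy <- if (amplified) {
    comp$clean + comp$env + acquisition / amp$gain
  } else {
    comp$clean + comp$env + acquisition
  }
  out <- tibble::tibble(
    analyte = cls$name,
    label = ifelse(cls$virus_present, "virus_present", "virus_absent"),
    carrier_freq = carrier_freq,
    occupancy = comp$occupancy,
    isd = comp$isd,
    seed = as.integer(seed),
    clean = list(comp$clean),
    noisy = list(noisy)
  )
  attr(out, "fs") <- fs
  attr(out, "T") <- as.integer(T)
  class(out) <- c("sinw_window", class(out))
  out
}

# Exposed for the noise-decomposition property: the raw additive components.
#' Noise components of one window
#'
#' Returns the individual additive noise components (and the clean trace) that
#' [synthesize_window()] sums, for decomposition diagnostics.
#' @inheritParams synthesize_window
#' @return A named list of numeric vectors.
#' @keywords internal
#' @export
window_noise_components <- function(circuit = impedance_model(), cls = "blank",
                                    noise, amp = amplifier_model(),
                                    carrier_freq, T = 1024, fs = 15e6, seed = 1,
                                    drive = drive_params(), modulation_depth = 1e-4,
                                    ref_freq = 6e3, occupancy_cv = 0.02) {
  if (is.character(cls)) cls <- analyte_class(cls)
  window_components(cls, noise, amp, carrier_freq, T, fs, seed,
                    circuit, drive, modulation_depth, ref_freq, occupancy_cv)
}

split_counts <- function(n, classes, class_mix) {
  if (is.null(class_mix)) class_mix <- stats::setNames(rep(1, nrow(classes)), classes$name)
  class_mix <- class_mix[classes$name] / sum(class_mix)
  base <- floor(n * class_mix)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(n * class_mix - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  base
}

#' Generate the labelled benchmark dataset
#'
#' Builds seeded train/validation/test splits of noisy/clean window pairs,
#' stratified over the carrier-frequency grid and the five analyte classes.
#' Windows of the two target classes are labelled `virus_present`; blank,
#' non-specific and cross-reactive windows are `virus_absent`. The same
#' `master_seed` reproduces the dataset bitwise.
#'
#' @param n_train,n_val,n_test Windows per split (positive).
#' @param freq_grid Carrier frequencies (Hz), all inside `(0, fs/2)`.
#' @param class_mix Optional named weights over analyte classes (default
#'   uniform).
#' @param T Window length (samples).
#' @param fs Sampling rate (Hz).
#' @param master_seed Integer master seed.
#' @param circuit,drive,amp Component models.
#' @param modulation_depth,snr_db_band,occupancy_cv Generator calibration
#'   parameters (see [calibrated_noise_model()]).
#' @param classes Analyte class table.
#'
#' @return A tibble of class `sinw_benchmark` with one row per window and
#'   columns `split`, `window_id`, `analyte`, `label`, `carrier_freq`,
#'   `occupancy`, `isd`, `seed`, `clean`, `noisy`; generator settings are
#'   stored in attributes (`fs`, `T`, `freq_grid`, `master_seed`, `generator`).
#' @examples
#' \donttest{
#' bench <- make_benchmark(n_train = 50, n_val = 20, n_test = 20, master_seed = 1)
#' }
#' @export
make_benchmark <- function(n_train = 2000, n_val = 500, n_test = 500,
                           freq_grid = default_freq_grid(),
                           class_mix = NULL, T = 1024, fs = 15e6,
                           master_seed = 42,
                           circuit = impedance_model(), drive = drive_params(),
                           amp = amplifier_model(),
                           modulation_depth = 1e-4, snr_db_band = c(46, 56),
                           occupancy_cv = 0.02,
                           classes = analyte_classes()) {
  stopifnot(n_train > 0, n_val > 0, n_test > 0)
  if (any(freq_grid >= fs / 2)) abort("freq_grid violates Nyquist")

  noise_by_freq <- lapply(freq_grid, calibrated_noise_model, fs = fs, T = T,
                          circuit = circuit, drive = drive,
                          modulation_depth = modulation_depth,
                          snr_db_band = snr_db_band)
  names(noise_by_freq) <- as.character(freq_grid)

  splits <- c(train = n_train, val = n_val, test = n_test)
  set.seed(master_seed)
  seeds <- sample.int(.Machine$integer.max - 1L, sum(splits))

  rows <- vector("list", sum(splits))
  r <- 0L
  for (sp in names(splits)) {
    n <- splits[[sp]]
    counts <- split_counts(n, classes, class_mix)
    plan_class <- rep(classes$name, counts)
    # within each class, cycle over the frequency grid for stratification
    plan_freq <- unlist(lapply(counts, function(k) {
      freq_grid[(seq_len(k) - 1L) %% length(freq_grid) + 1L]
    }), use.names = FALSE)
    for (i in seq_len(n)) {
      r <- r + 1L
      f <- plan_freq[i]
      w <- synthesize_window(
        circuit = circuit, cls = plan_class[i],
        noise = noise_by_freq[[as.character(f)]], amp = amp,
        carrier_freq = f, T = T, fs = fs, seed = seeds[r],
        drive = drive, modulation_depth = modulation_depth,
        occupancy_cv = occupancy_cv
      )
      w$split <- sp
      rows[[r]] <- w
    }
  }
  ds <- dplyr::bind_rows(rows)
  ds$window_id <- seq_len(nrow(ds))
  ds <- dplyr::relocate(ds, "split", "window_id")

  attr(ds, "fs") <- fs
  attr(ds, "T") <- as.integer(T)
  attr(ds, "freq_grid") <- freq_grid
  attr(ds, "master_seed") <- as.integer(master_seed)
  attr(ds, "generator") <- list(
    n_train = n_train, n_val = n_val, n_test = n_test,
    modulation_depth = modulation_depth, ref_freq = 6e3,
    snr_db_band = snr_db_band, occupancy_cv = occupancy_cv,
    class_mix = class_mix,
    circuit = unclass(circuit), drive = unclass(drive), amp = unclass(amp)
  )
  class(ds) <- c("sinw_benchmark", class(ds))
  ds
}

#' @export
print.sinw_benchmark <- function(x, ...) {
  cat(sprintf("<sinw_benchmark> %d windows (T = %d, fs = %.3g Hz, %d carriers)\n",
              nrow(x), attr(x, "T"), attr(x, "fs"), length(attr(x, "freq_grid"))))
  print(tibble::as_tibble(x), ...)
  invisible(x)
}

# Subset a benchmark while keeping generator attributes.
benchmark_split <- function(ds, split) {
  keep <- ds$split %in% split
  out <- ds[keep, ]
  for (a in c("fs", "T", "freq_grid", "master_seed", "generator")) {
    attr(out, a) <- attr(ds, a)
  }
  class(out) <- class(ds)
  out
}

#' Pre-denoising SNR profile of a dataset
#'
#' Mean clean-referenced SNR of the noisy traces per carrier frequency.
#' Windows with exactly zero residual report the `Inf` sentinel.
#'
#' @param dataset A `sinw_benchmark`.
#' @param split Splits to include (default all).
#' @return A tibble with columns `carrier_freq`, `snr_db`, `n`.
#' @export
snr_profile <- function(dataset, split = unique(dataset$split)) {
  ds <- dataset[dataset$split %in% split, ]
  ds$snr <- purrr::map2_dbl(ds$clean, ds$noisy, snr_db)
  dplyr::summarise(dplyr::group_by(tibble::as_tibble(ds), .data$carrier_freq),
                   snr_db = mean(.data$snr), n = dplyr::n(), .groups = "drop")
}
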