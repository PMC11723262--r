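test_that("identical seeds give bitwise-identical windows, different seeds differ", {
  w1 <- synthesize_window(carrier_freq = 1e5, T = 512, seed = 7)
  w2 <- synthesize_window(carrier_freq = 1e5, T = 512, seed = 7)
  w3 <- synthesize_window(carrier_freq = 1e5, T = 512, seed = 8)
  expect_identical(w1$noisy[[1]], w2$noisy[[1]])
  expect_identical(w1$clean[[1]], w2$clean[[1]])
  expect_false(identical(w1$noisy[[1]], w3$noisy[[1]]))
})

test_that("with all noise sources at zero the noisy trace equals the clean trace", {
  w <- synthesize_window(
    cls = "target_high_affinity",
    noise = noise_model(),   # every field zero
    amp = amplifier_model(gain = 1, input_referred_noise_sigma = 0),
    carrier_freq = 2e5, T = 256, seed = 3, occupancy_cv = 0
  )
  expect_identical(w$noisy[[1]], w$clean[[1]])
})

test_that("synthesize_window validates Nyquist and window length", {
  expect_error(synthesize_window(carrier_freq = 8e6, fs = 15e6, seed = 1), "Nyquist")
  expect_error(synthesize_window(carrier_freq = 1e5, T = -4, seed = 1), "positive integer")
})

test_that("benchmark SNR profile sits in the 45-60 dB band and rises with frequency", {
  b <- tiny_benchmark()
  p <- snr_profile(b)
  expect_true(all(p$snr_db >= 45 & p$snr_db <= 60))
  # rising trend on the log grid (tolerate small per-point wobble)
  expect_gt(p$snr_db[nrow(p)], p$snr_db[1] + 5)
  expect_true(all(diff(p$snr_db) > -1))
})

test_that("doubling the white noise sigma costs 6.02 dB when white noise dominates", {
  nm1 <- noise_model(white_sigma = 2e-8)
  nm2 <- noise_model(white_sigma = 4e-8)
  w1 <- synthesize_window(noise = nm1, carrier_freq = 1e5, T = 512, seed = 5,
                          amp = amplifier_model(input_referred_noise_sigma = 0))
  w2 <- synthesize_window(noise = nm2, carrier_freq = 1e5, T = 512, seed = 5,
                          amp = amplifier_model(input_referred_noise_sigma = 0))
  d1 <- snr_db(w1$clean[[1]], w1$noisy[[1]])
  d2 <- snr_db(w2$clean[[1]], w2$noisy[[1]])
  expect_equal(d1 - d2, 20 * log10(2), tolerance = 1e-6)
})

test_that("noise components are additive: total power equals the sum of parts", {
  # long window so cross terms between independent components average out
  f <- 3e5
  nm <- calibrated_noise_model(f, T = 65536)
  nm$nonlinear_mix <- 0
  comp <- window_noise_components(noise = nm, carrier_freq = f, T = 65536, seed = 9)
  parts <- list(comp$white, comp$drift, comp$tones, comp$bursts, comp$env)
  total <- Reduce(`+`, parts)
  p_total <- mean(total^2)
  p_sum <- sum(vapply(parts, function(v) mean(v^2), numeric(1)))
  expect_lt(abs(p_total - p_sum) / p_sum, 0.01)
})

test_that("stratification spreads windows uniformly over classes and labels follow the rule", {
  b <- tiny_benchmark()
  te <- b[b$split == "test", ]
  counts <- table(te$analyte)
  expect_true(all(counts == nrow(te) / 5))
  expect_true(all(b$label[b$analyte %in% c("target_high_affinity", "target_low_affinity")]
                  == "virus_present"))
  expect_true(all(b$label[b$analyte %in% c("blank", "non_specific", "cross_reactive")]
                  == "virus_absent"))
})

test_that("the same master seed reproduces the dataset bitwise", {
  b1 <- make_benchmark(n_train = 12, n_val = 6, n_test = 12, T = 128, master_seed = 31)
  b2 <- make_benchmark(n_train = 12, n_val = 6, n_test = 12, T = 128, master_seed = 31)
  expect_identical(b1$noisy, b2$noisy)
  expect_identical(b1$clean, b2$clean)
  expect_identical(b1$seed, b2$seed)
})

test_that("an oracle denoiser has unbounded headroom on every window", {
  b <- tiny_benchmark()
  d <- apply_method(sinwfet:::benchmark_split(b, "test"), "oracle")
  imp <- purrr::pmap_dbl(list(d$clean, d$noisy, d$denoised), snr_improvement_db)
  expect_true(all(imp >= 35))
})

test_that("clean traces carry the binding level: target classes exceed the threshold", {
  b <- tiny_benchmark()
  env_mean <- vapply(b$clean, mean, numeric(1))
  present <- b$label == "virus_present"
  expect_true(all(env_mean[present] > 11e-6))
  expect_true(all(env_mean[!present] < 11e-6))
})
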