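test_that("moving average matches the brute-force oracle with symmetric edges", {
  expect_equal(moving_average(c(1, 2, 3, 4, 5), 3),
               c(4 / 3, 2, 3, 4, 14 / 3), tolerance = 1e-12)
  set.seed(21)
  for (w in c(3, 5, 9)) {
    x <- rnorm(40)
    expect_equal(moving_average(x, w), ma_oracle(x, w), tolerance = 1e-12)
  }
})

test_that("moving average basics: identity, constants, validation", {
  x <- rnorm(20)
  expect_identical(moving_average(x, 1), x)
  expect_equal(moving_average(rep(2.5, 30), 7), rep(2.5, 30))
  expect_error(moving_average(x, 4), "odd")
  expect_error(moving_average(x, 21), "length")
})

test_that("both filters are linear operators", {
  set.seed(22)
  x <- rnorm(512); y <- rnorm(512)
  a <- 1.7; b <- -0.4
  ma <- function(v) moving_average(v, 5)
  lp <- function(v) low_pass(v, fs = 1e6, cutoff = 5e4, order = 4)
  for (f in list(ma, lp)) {
    lhs <- f(a * x + b * y)
    rhs <- a * f(x) + b * f(y)
    expect_lt(max(abs(lhs - rhs)) / max(abs(lhs)), 1e-9)
  }
})

test_that("low-pass matches the analytic zero-phase Butterworth response", {
  # probes sit at low normalized frequency so the bilinear-transform warping
  # of the digital filter is negligible against the analog formula
  fs <- 15e6; co <- 1e5; order <- 4
  T <- 16384
  t <- (0:(T - 1)) / fs
  core <- (T / 4):(3 * T / 4)   # steady-state region away from the edges
  for (ratio in c(0.01, 0.5, 1, 2)) {
    f <- ratio * co
    x <- sin(2 * pi * f * t)
    y <- low_pass(x, fs, co, order)
    g_meas <- sqrt(mean(y[core]^2) / mean(x[core]^2))
    g_ana <- butterworth_zero_phase_gain(f, co, order)
    expect_lt(abs(g_meas - g_ana) / g_ana, 0.01)
  }
  # tone at 10x cutoff, order 4: attenuated far beyond 60 dB
  x <- sin(2 * pi * 10 * co * t)
  y <- low_pass(x, fs, co, order)
  expect_lt(sqrt(mean(y[core]^2) / mean(x[core]^2)), 1e-3)
})

test_that("low-pass has exact unit DC gain and validates the cutoff", {
  x <- rep(3.2e-6, 1024)
  expect_equal(low_pass(x, 15e6, 1e5, 4), x, tolerance = 1e-12)
  expect_error(low_pass(x, 15e6, 7.5e6, 4), "cutoff")
  expect_error(low_pass(x, 15e6, 8e6, 4), "cutoff")
})

test_that("preamp pathway with unit gain reproduces the raw pathway exactly", {
  b <- tiny_benchmark()
  sub <- sinwfet:::benchmark_split(b, "test")[1:8, ]
  attr(sub, "generator") <- attr(b, "generator")
  attr(sub, "fs") <- attr(b, "fs"); attr(sub, "T") <- attr(b, "T")
  attr(sub, "freq_grid") <- attr(b, "freq_grid")
  gen <- attr(b, "generator")
  amp1 <- amplifier_model(gain = 1,
                          input_referred_noise_sigma = gen$amp$input_referred_noise_sigma,
                          post_gain_noise_sigma = gen$amp$post_gain_noise_sigma)
  re <- preamp_only(sub, amp = amp1)
  for (i in seq_len(nrow(sub))) expect_equal(re[[i]], sub$noisy[[i]], tolerance = 1e-15)
})

test_that("raising the gain drives the preamp pathway toward its input-noise ceiling", {
  b <- tiny_benchmark()
  sub <- sinwfet:::benchmark_split(b, "test")[1:10, ]
  snr_at_gain <- function(g) {
    amp <- amplifier_model(gain = g, input_referred_noise_sigma = 2e-9)
    re <- preamp_only(sub, amp = amp)
    mean(purrr::map2_dbl(sub$clean, re, snr_db))
  }
  s1 <- snr_at_gain(10); s2 <- snr_at_gain(100); s3 <- snr_at_gain(1e5)
  expect_lt(s1, s2)
  expect_lt(s2, s3 + 0.01)
  expect_lt(s3 - s2, 3)   # already near the ceiling at the default gain
})

test_that("preamp-only SNR sits in the published 70-80 dB band", {
  b <- tiny_benchmark()
  te <- sinwfet:::benchmark_split(b, "test")
  d <- apply_method(te, "preamp_only")
  per_freq <- tapply(purrr::map2_dbl(d$clean, d$denoised, snr_db),
                     d$carrier_freq, mean)
  expect_true(all(per_freq >= 70 & per_freq <= 80))
})
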