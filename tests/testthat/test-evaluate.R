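test_that("snr_db agrees with a direct-summation oracle", {
  set.seed(11)
  for (i in 1:20) {
    clean <- rnorm(200) + 2
    est <- clean + rnorm(200, sd = runif(1, 0.001, 1))
    oracle <- 10 * log10(sum(clean * clean) / sum((est - clean) * (est - clean)))
    expect_equal(snr_db(clean, est), oracle, tolerance = 1e-9)
  }
})

test_that("snr_db sentinels and errors", {
  x <- sin(1:50)
  expect_identical(snr_db(x, x), Inf)
  # residual power equal to clean power gives 0 dB
  resid <- rnorm(50)
  resid <- resid * sqrt(sum(x^2) / sum(resid^2))
  expect_equal(snr_db(x, x + resid), 0, tolerance = 1e-9)
  expect_error(snr_db(numeric(50), x), "zero power")
  expect_error(snr_db(x, x[1:10]), "lengths differ")
})

test_that("snr_db recovers the analytic ratio for a unit sine plus scaled noise", {
  t <- seq(0, 1, length.out = 1e4 + 1)[-1]
  clean <- sin(2 * pi * 25 * t)          # power 0.5
  set.seed(2)
  e <- rnorm(length(t))
  e <- e * sqrt(0.005 * length(t) / sum(e^2))  # residual power exactly 0.005
  expect_equal(snr_db(clean, clean + e),
               10 * log10(mean(clean^2) / 0.005), tolerance = 1e-9)
  expect_equal(snr_db(clean, clean + e), 20, tolerance = 0.01)
})

test_that("noise_reduction_fraction definition and trivial cases", {
  set.seed(3)
  clean <- rnorm(100); noisy <- clean + rnorm(100)
  expect_equal(noise_reduction_fraction(clean, noisy, clean), 1)
  expect_equal(noise_reduction_fraction(clean, noisy, noisy), 0)
  # residual power reduced 4x => 0.75
  den <- clean + (noisy - clean) / 2
  expect_equal(noise_reduction_fraction(clean, noisy, den), 0.75, tolerance = 1e-12)
  expect_error(noise_reduction_fraction(clean, clean, clean), "zero")
})

test_that("improvement and fraction satisfy the exact log identity", {
  set.seed(4)
  for (i in 1:50) {
    clean <- rnorm(64) + 1
    noisy <- clean + rnorm(64, sd = 0.5)
    den <- clean + rnorm(64, sd = runif(1, 0.01, 2))  # can be worse than input
    fr <- noise_reduction_fraction(clean, noisy, den)
    imp <- snr_improvement_db(clean, noisy, den)
    expect_equal(imp, -10 * log10(1 - fr), tolerance = 1e-9)
  }
})

test_that("snr improvement is invariant to common rescaling", {
  set.seed(5)
  clean <- rnorm(64) + 2; noisy <- clean + rnorm(64, sd = .1)
  den <- clean + rnorm(64, sd = .02)
  expect_equal(snr_improvement_db(clean, noisy, den),
               snr_improvement_db(clean * 3.7, noisy * 3.7, den * 3.7),
               tolerance = 1e-9)
  # 75% noise-power reduction is about 6.02 dB of SNR improvement
  den4 <- clean + (noisy - clean) / 2
  expect_equal(snr_improvement_db(clean, noisy, den4), 10 * log10(4),
               tolerance = 1e-9)
})

test_that("detection rule uses a strict 11 uA threshold on the envelope mean", {
  expect_identical(detect_virus(rep(12e-6, 64)), "virus_present")
  expect_identical(detect_virus(rep(11e-6, 64)), "virus_absent")
  expect_identical(detect_virus(rep(9e-6, 64)), "virus_absent")
})

test_that("confusion metrics match a hand-built oracle", {
  truth <- c("virus_present", "virus_present", "virus_present",
             "virus_absent", "virus_absent", "virus_absent", "virus_absent")
  call <- c("virus_present", "virus_absent", "virus_present",
            "virus_absent", "virus_present", "virus_absent", "virus_absent")
  m <- sinwfet:::confusion_metrics(truth, call)
  # by hand: TP 2, FN 1, TN 3, FP 1
  expect_equal(m$tp, 2); expect_equal(m$fn, 1)
  expect_equal(m$tn, 3); expect_equal(m$fp, 1)
  expect_equal(m$accuracy, 5 / 7)
  expect_equal(m$sensitivity, 2 / 3)
  expect_equal(m$specificity, 3 / 4)
  expect_equal(m$cross_reactivity_rate, 1 / 4)
})

test_that("evaluate_methods handles oracle/identity bounds and bad names", {
  b <- tiny_benchmark()
  rep <- evaluate_methods(b, methods = c("oracle", "identity"))
  orc <- rep$summary[rep$summary$method == "oracle", ]
  ident <- rep$summary[rep$summary$method == "identity", ]
  expect_equal(orc$noise_reduction_fraction, 1)
  expect_identical(orc$snr_improvement_db, Inf)
  expect_equal(ident$snr_improvement_db, 0)
  expect_equal(ident$noise_reduction_fraction, 0)
  expect_true(all(rep$summary$accuracy >= 0 & rep$summary$accuracy <= 1))
  expect_error(evaluate_methods(b, methods = "wavelet"), "unknown method")
})
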