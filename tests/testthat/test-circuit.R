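test_that("impedance matches an independent complex-arithmetic oracle", {
  zm <- impedance_model()
  freqs <- 10^seq(0, 9, length.out = 100)
  z_pkg <- impedance(zm, freqs)
  z_orc <- impedance_oracle(zm$Rs, zm$Cs, zm$Rp, zm$Cp, freqs)
  expect_lt(max(Mod(z_pkg - z_orc) / Mod(z_orc)), 1e-9)
})

test_that("impedance limits: capacitors short at high frequency, series Cs blocks DC", {
  zm <- impedance_model(Rs = 1e3, Cs = 1e-9, Rp = 1e4, Cp = 1e-10)
  expect_lt(Mod(impedance(zm, 1e14) - 1e3) / 1e3, 1e-4)
  expect_gt(Mod(impedance(zm, 1e-8)), 1e12)
})

test_that("|Z| is non-increasing over the 6 kHz-6 MHz band for default elements", {
  f <- default_freq_grid(200)
  expect_true(all(diff(Mod(impedance(impedance_model(), f))) <= 0))
})

test_that("impedance domain errors", {
  expect_error(impedance(impedance_model(), 0), "positive")
  expect_error(impedance(impedance_model(), -5), "positive")
  expect_error(impedance_model(Rs = -1), "positive")
  expect_error(impedance_model(Cs = 0), "positive")
  expect_error(impedance_model(Rp = Inf), "positive")
})

test_that("binding time course follows the Langmuir closed form", {
  cls <- tibble::tibble(name = "custom", equilibrium_occupancy = 1,
                        response_coefficient = 1,
                        association_time_constant = 5, virus_present = TRUE)
  tc <- binding_time_course(cls, duration = 5, n_points = 2)
  expect_equal(tc$occupancy[1], 0)
  expect_equal(tc$occupancy[2], 1 - exp(-1), tolerance = 1e-12)

  # monotone non-decreasing and bounded by the equilibrium occupancy
  for (nm in analyte_classes()$name) {
    tc <- binding_time_course(nm, duration = 2000, n_points = 200)
    expect_true(all(diff(tc$occupancy) >= 0))
    expect_lte(max(tc$occupancy), analyte_class(nm)$equilibrium_occupancy)
  }
})

test_that("asymptotic impedance changes match the calibrated class table", {
  asym <- function(nm) {
    cls <- analyte_class(nm)
    tail(binding_time_course(nm, duration = 100 * cls$association_time_constant,
                             n_points = 10)$impedance_change, 1)
  }
  expect_equal(asym("target_high_affinity"), 0.92, tolerance = 1e-6)
  expect_equal(asym("target_low_affinity"), 0.78, tolerance = 1e-6)
  expect_equal(asym("non_specific"), 0.05, tolerance = 1e-6)
  expect_equal(asym("cross_reactive"), 0.07, tolerance = 1e-6)
  expect_equal(asym("blank"), 0)
})

test_that("blank class produces zero impedance change at all times", {
  tc <- binding_time_course("blank", duration = 1e4, n_points = 50)
  expect_true(all(tc$impedance_change == 0))
  expect_true(all(tc$isd == drive_params()$Vds * drive_params()$G0))
})

test_that("isd_from_state is linear and calibrated around the 11 uA rule", {
  drv <- drive_params()
  base <- isd_from_state(0, drv)
  expect_equal(base, 10e-6)
  # strictly increasing in impedance change
  d <- seq(0, 1, by = 0.05)
  expect_true(all(diff(isd_from_state(d, drv)) > 0))
  # doubling the transduction gain doubles the current excess
  drv2 <- drive_params(transduction_gain = 2 * drv$transduction_gain)
  expect_equal(isd_from_state(0.4, drv2) - base,
               2 * (isd_from_state(0.4, drv) - base), tolerance = 1e-12)
  # high-affinity equilibrium crosses the detection threshold, blank and
  # non-specific stay below it
  expect_gt(isd_from_state(0.92, drv), 11e-6)
  expect_equal(isd_from_state(0.92, drv), 12.5e-6, tolerance = 1e-9)
  expect_lt(isd_from_state(0.05, drv), 10.6e-6)
  expect_lt(base, 11e-6)
})

test_that("binding_time_course input validation", {
  expect_error(binding_time_course("blank", duration = -1, n_points = 10), "positive")
  expect_error(binding_time_course("blank", duration = 10, n_points = 1), "at least 2")
})
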