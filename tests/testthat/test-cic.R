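test_that("central differences are exact for polynomials up to degree 2", {
  expect_equal(central_difference(rep(3, 10), 0.1), rep(0, 10))
  x <- seq(0, 1, by = 0.1)
  d <- central_difference(5 * x, 0.1)
  expect_equal(d, rep(5, length(x)), tolerance = 1e-12)
  dq <- central_difference(x^2, 0.1)
  expect_equal(dq[2:(length(x) - 1)], 2 * x[2:(length(x) - 1)],
               tolerance = 1e-12)
  expect_error(central_difference(c(1, 2), 0.1), "3 samples")
})

# noise-free Ohmic trace with known switching times
ohmic_trace <- function(n_pulses = 1, fs = 1e6, amp_v = 0.5) {
  train <- pulse_train(50e-6, pulses_per_burst = n_pulses)
  tr <- simulate_transient(circuit_params(amp_v / 50e-6, Inf, 1), train)
  tr
}

test_that("pulse edges are found at the known switching times", {
  tr1 <- ohmic_trace(1)
  e1 <- detect_pulse_edges(tr1)
  expect_equal(nrow(e1), 4)
  expect_equal(e1$time[1], 2e-3, tolerance = 2e-6)
  expect_equal(e1$time[2], 2.6e-3, tolerance = 2e-6)
  expect_equal(e1$time[3], 2.8e-3, tolerance = 2e-6)
  expect_equal(e1$time[4], 3.4e-3, tolerance = 2e-6)

  e5 <- detect_pulse_edges(ohmic_trace(5))
  expect_equal(nrow(e5), 20)

  flat <- structure(list(time = seq(0, 1e-3, by = 1e-6),
                         voltage = rep(0.1, 1001)),
                    class = "voltage_transient")
  expect_error(detect_pulse_edges(flat), "no pulses found")
})

test_that("the polarization bias is the pre-pulse mean", {
  tr <- ohmic_trace(1)
  tr$voltage <- tr$voltage + 0.1
  expect_equal(estimate_eipp(tr), 0.1, tolerance = 1e-12)

  set.seed(12)
  noisy <- structure(list(time = seq(0, 10e-3, by = 1e-6),
                          voltage = rnorm(10001, 0, 1e-3),
                          first_onset = 10e-3),
                     class = "voltage_transient")
  expect_lt(abs(estimate_eipp(noisy)), 3 * 1e-3 / sqrt(10000))

  sim <- simulate_transient(circuit_params(1e4, 1e6, 1e-7),
                            pulse_train(50e-6), polarization_offset = 0.2)
  expect_equal(estimate_eipp(sim), 0.2, tolerance = 1e-6)

  short <- ohmic_trace(1)
  expect_error(estimate_eipp(short, first_onset = 5e-6), "10 samples")
})

test_that("interface isolation removes the access steps", {
  # Ohmic-only trace: everything is access voltage
  tr <- ohmic_trace(1)
  an <- isolate_interface_voltage(tr)
  expect_equal(max(abs(an$interface_voltage)), 0, tolerance = 1e-6)
  expect_equal(an$emc, 0, tolerance = 1e-6)
  expect_equal(an$ema, 0, tolerance = 1e-6)
  expect_equal(an$access_voltage_cathodic, 0.5, tolerance = 0.02)

  # alpha = 1: access voltage recovered within 2% of I Rs
  p <- circuit_params(1e4, 1e6, 100e-9)
  tr2 <- simulate_transient(p, pulse_train(50e-6), polarization_offset = 0.15)
  an2 <- isolate_interface_voltage(tr2)
  expect_equal(an2$access_voltage_cathodic, 50e-6 * 1e4, tolerance = 0.02)
  expect_equal(an2$access_voltage_anodic, 50e-6 * 1e4, tolerance = 0.02)
  expect_equal(an2$eipp, 0.15, tolerance = 1e-6)

  # polarity mirror symmetry: anodic-first trace mirrors cathodic-first
  tr_a <- simulate_transient(p, pulse_train(50e-6, cathodic_first = FALSE))
  an_a <- isolate_interface_voltage(tr_a)
  expect_equal(an_a$ema, -an2$emc, tolerance = 0.02)
  expect_equal(an_a$emc, -an2$ema, tolerance = 0.02)
})

test_that("burst extrema match the closed-form RC recursion oracle", {
  p <- circuit_params(5e3, 2e4, 2e-6)
  amp <- 200e-6
  tr <- simulate_transient(p, pulse_train(amp))
  an <- isolate_interface_voltage(tr)
  orc <- rc_burst_extrema(amp, p$rs, p$rct, p$cap,
                          pw = 0.6e-3, gap = 200e-6,
                          n_pulses = 5, pulse_freq = 500)
  expect_equal(an$emc, orc$emc, tolerance = 0.02)
  expect_equal(an$ema, orc$ema, tolerance = 0.02)
})

test_that("interface voltage of a balanced burst starts and ends near zero", {
  p <- circuit_params(1e3, 1e4, 1e-6)
  tr <- simulate_transient(p, pulse_train(100e-6), polarization_offset = 0.1,
                           tail = 50e-3)
  an <- isolate_interface_voltage(tr)
  n <- length(an$interface_voltage)
  expect_equal(an$interface_voltage[1], 0, tolerance = 1e-4)
  # after the 5-tau tail the residual is bounded by the e^-5 decay
  expect_lt(abs(an$interface_voltage[n]), 1.1 * abs(an$emc) * exp(-5))
})

test_that("recovered extrema scale linearly with current", {
  p <- circuit_params(2e3, 5e4, 5e-7)
  amps <- c(20e-6, 40e-6, 80e-6)
  emc <- vapply(amps, function(a) {
    isolate_interface_voltage(simulate_transient(p, pulse_train(a)))$emc
  }, numeric(1))
  expect_equal(emc[2] / emc[1], 2, tolerance = 0.02)
  expect_equal(emc[3] / emc[1], 4, tolerance = 0.02)
})

test_that("water-window compliance uses the closed interval", {
  an <- structure(list(emc = -0.48, ema = 0.31), class = "transient_analysis")
  cw <- check_water_window(an, water_window())
  expect_true(cw$compliant)
  expect_equal(cw$margin_low, 0.42)
  expect_equal(cw$margin_high, 0.29)

  an2 <- structure(list(emc = -0.95, ema = 0.31), class = "transient_analysis")
  cw2 <- check_water_window(an2)
  expect_false(cw2$compliant)
  expect_equal(cw2$margin_low, -0.05)

  an3 <- structure(list(emc = -0.9, ema = 0.6), class = "transient_analysis")
  expect_true(check_water_window(an3)$compliant)
})

test_that("charge-injection capacity follows I pw / GSA", {
  expect_equal(charge_injection_capacity(50e-6, 0.6e-3, electrode_geometry(40)),
               2.387, tolerance = 1e-3)
  expect_equal(charge_injection_capacity(50e-6, 0.6e-3, electrode_geometry(20)),
               9.549, tolerance = 1e-3)
  expect_equal(charge_injection_capacity(100e-6, 0.6e-3, electrode_geometry(40)),
               2 * charge_injection_capacity(50e-6, 0.6e-3, electrode_geometry(40)))
  expect_error(charge_injection_capacity(0, 1e-3, electrode_geometry(20)),
               "positive")
})

test_that("the current ramp finds the planted compliance threshold", {
  p <- circuit_params(1e3, 1e4, 1e-6)
  train <- pulse_train(1e-6)
  geom <- electrode_geometry(20)
  sim <- function(tr) simulate_transient(p, tr)
  amps <- seq(0.5e-3, 3e-3, by = 0.5e-3)
  res <- cic_ramp(sim, train, amps, water_window(), geom)
  # independent oracle: closed-form extrema per amplitude
  ok <- vapply(amps, function(a) {
    o <- rc_burst_extrema(a, p$rs, p$rct, p$cap, 0.6e-3, 200e-6, 5, 500)
    o$emc >= -0.9 && o$ema <= 0.6
  }, logical(1))
  expect_true(any(ok) && !all(ok))   # the threshold is inside the sweep
  expect_equal(res$max_safe_current, max(amps[ok]))
  expect_equal(res$charge_injection_capacity,
               charge_injection_capacity(max(amps[ok]), 0.6e-3, geom))

  # unconstrained window: the last amplitude is compliant
  wide <- cic_ramp(sim, train, amps, water_window(-10, 10), geom)
  expect_equal(wide$max_safe_current, max(amps))

  # nothing compliant
  none <- cic_ramp(sim, train, amps, water_window(-1e-4, 1e-4), geom)
  expect_true(none$none_compliant)
  expect_true(is.na(none$charge_injection_capacity))

  expect_error(cic_ramp(sim, train, numeric(0), water_window(), geom), "empty")
  expect_error(cic_ramp(sim, train, c(2e-3, 1e-3), water_window(), geom),
               "increasing")
})
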