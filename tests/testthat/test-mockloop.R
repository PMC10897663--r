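test_that("Moens-Korteweg wave speed has the right value and scaling", {
  # identity: E*h = 2*rho*r -> c = 1 m/s
  expect_equal(moens_korteweg(E = 2000, h = 1, r = 1, rho = 1000), 1)
  # sqrt scaling in E and 1/sqrt in r
  c1 <- moens_korteweg(300e3, 2e-3, 10e-3)
  expect_equal(moens_korteweg(4 * 300e3, 2e-3, 10e-3), 2 * c1)
  expect_equal(moens_korteweg(300e3, 2e-3, 4 * 10e-3), c1 / 2)
  # hand-evaluated: sqrt(400e3 * 2e-3 / (2 * 1000 * 11.4e-3)) = sqrt(800/22.8)
  expect_equal(moens_korteweg(400e3, 2e-3, 11.4e-3, 1000),
               sqrt(800 / 22.8), tolerance = 1e-12)
  expect_error(moens_korteweg(-1, 2e-3, 1e-2), "positive")
  expect_error(moens_korteweg(1e5, 0, 1e-2), "positive")
})

test_that("windkessel tuning reaches the physiologic pressure windows", {
  cfg <- mockloop_config(noise_sd = 0)
  tuned <- tune_windkessel(cfg)
  w <- cfg$pressure_windows
  for (nm in names(w)) {
    expect_gte(tuned$pressures[[nm]], w[[nm]][1])
    expect_lte(tuned$pressures[[nm]], w[[nm]][2])
  }
  # unattainable window errors and names the offender
  bad <- mockloop_config(pressure_windows = list(
    DBP = c(75, 85), SBP = c(115, 125), PP = c(40, 50), MAP = c(90, 100)),
    map_target = 95, pp_target = 80)
  expect_error(tune_windkessel(bad), "window")
})

test_that("simulated acquisitions honor flow, pressure and delay ground truth", {
  s <- ref_sample()
  cfg <- mockloop_config(noise_sd = 0)
  acq <- simulate_sample(s, cfg)
  # time-averaged proximal flow within 2% of the set cardiac output
  expect_lt(abs(mean(acq$proximal$values) / cfg$cardiac_output_target - 1),
            0.02)
  expect_equal(mean(acq$distal$values), mean(acq$proximal$values),
               tolerance = 1e-4)
  # zone-3 MAP lands inside the 90-100 mmHg window
  ps <- pressure_summary(acq$zone3)
  expect_gte(ps$MAP, 90); expect_lte(ps$MAP, 100)
  expect_gte(ps$DBP, 75); expect_lte(ps$DBP, 85)
  expect_gte(ps$SBP, 115); expect_lte(ps$SBP, 125)
  # noise-free cross-correlation lag matches the imposed transit time
  tt <- estimate_transit_time(acq$proximal, acq$distal)
  expect_lt(abs(tt$transit_time - acq$truth$true_transit_time),
            1 / cfg$sampling_rate)
})

test_that("the specimen wave speed is its Moens-Korteweg value at baseline", {
  s <- ref_sample()
  cfg <- mockloop_config(arch_stiffening_exponent = 0, noise_sd = 0)
  acq <- simulate_sample(s, cfg)
  expect_equal(acq$truth$true_wave_speed,
               moens_korteweg(s$E, s$h, s$d2 / 2000, s$rho),
               tolerance = 1e-12)
})

test_that("stent-graft shortens the transit time toward the covered-segment limit", {
  s <- ref_sample(length_slope = 0)
  base <- simulate_sample(s, null_effects_config(stent = FALSE))
  stented <- simulate_sample(s, null_effects_config(stent = TRUE))
  expect_lt(stented$truth$true_transit_time, base$truth$true_transit_time)
  # kappa -> infinity: covered 112 mm contributes nothing
  rigid <- simulate_sample(s, null_effects_config(
    stent = TRUE, stent_speed_factor = 1e9))
  c0 <- base$truth$true_wave_speed
  L <- base$truth$true_length_at_map_cm / 100
  expect_equal(rigid$truth$true_transit_time, (L - 0.112) / c0,
               tolerance = 1e-6)
})

test_that("noise-free delay recovery holds across the physiologic wave-speed range", {
  cfg <- null_effects_config()
  for (c_ms in c(2, 3, 4.5, 6)) {
    acq <- simulate_sample(sample_with_speed(c_ms), cfg)
    tt <- estimate_transit_time(acq$proximal, acq$distal)
    expect_lt(abs(tt$transit_time - acq$truth$true_transit_time),
              1 / cfg$sampling_rate)
  }
})

test_that("cohort generation is deterministic and tracks its population", {
  a <- generate_cohort(8, seed = 123)
  b <- generate_cohort(8, seed = 123)
  expect_identical(a, b)
  # zero-variance population collapses to the means
  pop0 <- cohort_population(d_sd = rep(0, 4), length_sd = 0,
                            length_slope_sd = 0, wave_speed_sd = 0)
  one <- generate_cohort(1, pop0, seed = 5)[[1]]
  expect_equal(c(one$d1, one$d2, one$d3, one$d4), pop0$d_mean)
  expect_equal(one$length_ref, pop0$length_mean)
  expect_equal(moens_korteweg(one$E, one$h, one$d2 / 2000, one$rho),
               pop0$wave_speed_mean, tolerance = 1e-12)
  # seed-averaged mean point-2 diameter near its population mean
  d2s <- unlist(lapply(1:5, function(k) {
    vapply(generate_cohort(24, seed = 100 + k), `[[`, numeric(1), "d2")
  }))
  expect_lt(abs(mean(d2s) - 22.8), 1)
  expect_error(generate_cohort(0), "positive")
})

test_that("configuration invariants are enforced", {
  expect_error(mockloop_config(n_cycles = 10), "25")
  expect_error(mockloop_config(sampling_rate = 50), "100 Hz")
  expect_error(mockloop_config(stent_speed_factor = 0.5), ">= 1")
  expect_error(mockloop_config(pressure_windows = list(
    DBP = c(85, 75), SBP = c(115, 125), PP = c(40, 50), MAP = c(90, 100))),
    "non-empty")
  expect_error(aorta_sample("x", 20, 22, 16, 14, 36), "taper")
})
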