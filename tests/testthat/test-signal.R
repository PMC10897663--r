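test_that("cycle segmentation counts complete cycles and rejects short records", {
  w <- waveform_record(sin(2 * pi * 75 / 60 * seq(0, 20, by = 1e-3)[-1]),
                       1000, "proximal", "flow", 75)
  ens <- segment_cycles(w)
  expect_equal(dim(ens$cycles), c(25, 800)) # 20 s * 75 bpm / 60
  w2 <- waveform_record(rnorm(60000), 1000, "proximal", "flow", 60)
  expect_equal(dim(segment_cycles(w2)$cycles), c(60, 1000))
  short <- waveform_record(rnorm(10000), 1000, "proximal", "flow", 75)
  expect_error(segment_cycles(short), "insufficient")
})

test_that("ensemble averaging is exact for identical cycles and suppresses noise", {
  cyc <- sin(2 * pi * (0:799) / 800)
  w <- waveform_record(rep(cyc, 25), 1000, "proximal", "flow", 75)
  expect_equal(ensemble_average(segment_cycles(w)), cyc, tolerance = 1e-12)
  one <- waveform_record(cyc, 1000, "proximal", "flow", 75)
  expect_equal(ensemble_average(segment_cycles(one, min_cycles = 1)), cyc)
  # residual SD after averaging 25 noisy cycles ~ sigma / 5
  set.seed(42)
  resid_sd <- replicate(20, {
    noisy <- waveform_record(rep(cyc, 25) + rnorm(20000, 0, 0.5), 1000,
                             "proximal", "flow", 75)
    sd(ensemble_average(segment_cycles(noisy)) - cyc)
  })
  expect_equal(mean(resid_sd), 0.5 / 5, tolerance = 0.1)
})

test_that("transit time recovers imposed integer and fractional delays", {
  # circular shift by exactly 100 samples
  cyc <- exp(-((0:799 / 800 - 0.3) / 0.08)^2)
  x <- rep(cyc, 25)
  y <- rep(c(cyc[701:800], cyc[1:700]), 25) # delayed by 100 samples
  wx <- waveform_record(x, 1000, "proximal", "flow", 75)
  wy <- waveform_record(y, 1000, "distal", "flow", 75)
  r <- estimate_transit_time(wx, wy)
  expect_equal(r$transit_time, 0.100, tolerance = 1e-4)
  expect_gt(r$peak_correlation, 0.99)
  # identical inputs: zero delay, flagged degenerate
  r0 <- estimate_transit_time(wx, wx)
  expect_true(r0$degenerate)
  expect_equal(r0$transit_time, 0)
  # fractional delay of 10.4 samples vs the 10x-upsampled oracle
  p <- pulse_pair(0.0104)
  est <- estimate_transit_time(p$prox, p$dist)$transit_time
  expect_equal(est, 0.0104, tolerance = 2e-4)
  expect_equal(est, oracle_delay(0.0104), tolerance = 2e-4)
})

test_that("transit time is shift-equivariant and amplitude-invariant", {
  p <- pulse_pair(0.0825)
  tt0 <- estimate_transit_time(p$prox, p$dist)$transit_time
  shift <- function(w, k) {
    v <- w$values
    waveform_record(c(v[-seq_len(k)], v[seq_len(k)]), w$sampling_rate,
                    w$site, w$channel, w$heart_rate)
  }
  tt_sh <- estimate_transit_time(shift(p$prox, 137),
                                 shift(p$dist, 137))$transit_time
  expect_equal(tt_sh, tt0, tolerance = 1e-6)
  scale_w <- function(w, a) waveform_record(a * w$values, w$sampling_rate,
                                            w$site, w$channel, w$heart_rate)
  tt_sc <- estimate_transit_time(scale_w(p$prox, 3.7),
                                 scale_w(p$dist, 0.2))$transit_time
  expect_equal(tt_sc, tt0, tolerance = 1e-9)
})

test_that("transit time rejects mismatched or unreliable inputs", {
  p <- pulse_pair(0.05)
  other <- waveform_record(p$dist$values, 500, "distal", "flow", 75)
  expect_error(estimate_transit_time(p$prox, other), "sampling rates")
  # uncorrelated noise: peak correlation below the floor
  set.seed(9)
  na <- waveform_record(rnorm(20000), 1000, "proximal", "flow", 75)
  nb <- waveform_record(rnorm(20000), 1000, "distal", "flow", 75)
  expect_error(estimate_transit_time(na, nb), "unreliable|degenerate")
})

test_that("pressure summaries follow the PP and MAP definitions", {
  # constant record: everything equal, PP zero
  const <- waveform_record(rep(100, 800), 1000, "zone3", "pressure", 75)
  ps <- pressure_summary(const)
  expect_equal(c(ps$DBP, ps$SBP, ps$PP, ps$MAP), c(100, 100, 0, 100))
  # sine over whole cycles: closed form
  t <- (0:(800 * 25 - 1)) / 1000
  sine <- waveform_record(100 + 20 * sin(2 * pi * t / 0.8), 1000, "zone3",
                          "pressure", 75)
  ps2 <- pressure_summary(sine)
  expect_equal(ps2$DBP, 80, tolerance = 1e-3)
  expect_equal(ps2$SBP, 120, tolerance = 1e-3)
  expect_equal(ps2$PP, 40, tolerance = 1e-3)
  expect_equal(ps2$MAP, 80 + 40 / 3, tolerance = 1e-3)
  # flow channel is refused
  flow <- waveform_record(rep(5, 800), 1000, "proximal", "flow", 75)
  expect_error(pressure_summary(flow), "pressure")
  # identities from systolic/diastolic values
  anchor <- pressure_from_sbp_dbp(122, 73)
  expect_equal(anchor$PP, 49)
  expect_equal(anchor$MAP, 73 + 49 / 3)
  expect_error(pressure_from_sbp_dbp(70, 80), "SBP")
})
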