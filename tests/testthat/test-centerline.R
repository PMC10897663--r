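make_pset <- function(points, scale_px = 100, pressure = 100) {
  planar_point_set(points, rbind(c(0, 0), c(scale_px, 0)), pressure)
}

test_that("pixel scale calibration follows the 2.5 cm reference line", {
  pts <- cbind(seq(0, 140, 10), 0)
  expect_equal(calibrate_scale(make_pset(pts, scale_px = 100)), 0.025)
  expect_equal(calibrate_scale(make_pset(pts, scale_px = 250)), 0.01)
  expect_error(planar_point_set(pts, rbind(c(1, 1), c(1, 1)), 100),
               "coincide")
})

test_that("polyline arc length matches closed forms and is isometry-invariant", {
  # 15 collinear points spanning 1448 px at 0.025 cm/px -> 36.2 cm
  line <- cbind(seq(0, 1448, length.out = 15), 5)
  expect_equal(arc_length(make_pset(line), 0.025), 36.2, tolerance = 1e-9)
  # semicircle radius 10 cm sampled at 101 points: chord sum vs pi * r
  th <- seq(0, pi, length.out = 101)
  semi <- cbind(10 * cos(th), 10 * sin(th)) # already in cm units
  l_semi <- arc_length(make_pset(semi, scale_px = 2.5), 1)
  chord_sum <- 2 * 100 * 10 * sin(pi / 200)
  expect_equal(l_semi, chord_sum, tolerance = 1e-9)
  expect_equal(l_semi, pi * 10, tolerance = 0.01 / (pi * 10))
  # rigid rotation leaves length unchanged
  a <- 0.7
  rot <- semi %*% matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2)
  expect_equal(arc_length(make_pset(rot, 2.5), 1), l_semi,
               tolerance = 1e-12)
  expect_error(planar_point_set(line[1:10, ], rbind(c(0, 0), c(10, 0)),
                                100), "15 points")
})

test_that("pressure-length regression matches ordinary least squares", {
  fit <- fit_length_pressure(c(80, 100, 120), c(36.0, 36.2, 36.4))
  expect_equal(fit$slope, 0.01, tolerance = 1e-12)
  expect_equal(fit$intercept, 35.2, tolerance = 1e-12)
  expect_equal(length_at(fit, 98), 36.18, tolerance = 1e-12)
  flat <- fit_length_pressure(c(80, 100, 120), rep(36.2, 3))
  expect_equal(flat$slope, 0)
  expect_equal(length_at(flat, 57), 36.2)
  # closed-form normal equations on 3 noisy points
  p <- c(80, 100, 120); l <- c(36.03, 36.25, 36.31)
  beta <- sum((p - mean(p)) * (l - mean(l))) / sum((p - mean(p))^2)
  alpha <- mean(l) - beta * mean(p)
  noisy <- fit_length_pressure(p, l)
  expect_equal(noisy$slope, beta, tolerance = 1e-10)
  expect_equal(noisy$intercept, alpha, tolerance = 1e-10)
  expect_error(fit_length_pressure(c(100, 100), c(36, 37)), "singular")
})

test_that("synthetic point sets encode the specimen length model", {
  s <- ref_sample()
  pset <- generate_point_set(s, 100, jitter_px = 0)
  expect_equal(arc_length(pset, calibrate_scale(pset)), 36.2,
               tolerance = 1e-9)
  # pressure dependence via the slope; none when slope is zero
  p120 <- generate_point_set(s, 120, jitter_px = 0)
  expect_equal(arc_length(p120, calibrate_scale(p120)), 36.4,
               tolerance = 1e-9)
  s0 <- ref_sample(length_slope = 0)
  lens <- vapply(c(80, 100, 120), function(p) {
    ps <- generate_point_set(s0, p, jitter_px = 0)
    arc_length(ps, calibrate_scale(ps))
  }, numeric(1))
  expect_equal(lens, rep(36.2, 3), tolerance = 1e-9)
  # calibrated length is invariant to image resolution
  hi <- generate_point_set(s, 100, px_per_cm = 80, jitter_px = 0)
  expect_equal(arc_length(hi, calibrate_scale(hi)), 36.2, tolerance = 1e-9)
  # jittered length stays within the stated placement-error bound
  for (sd_px in c(0.5, 2)) {
    for (sd_seed in 1:5) {
      pj <- generate_point_set(s, 100, px_per_cm = 40, jitter_px = sd_px,
                               n_points = 16, seed = sd_seed)
      bound <- 2 * sd_px * 15 / 40
      expect_lt(abs(arc_length(pj, calibrate_scale(pj)) - 36.2), bound)
    }
  }
  expect_error(generate_point_set(s, 100, n_points = 10), "15 points")
})

test_that("repeated operator measurements show excellent reliability", {
  # two jittered point sets of each of 24 specimens emulate the intra-
  # operator repeat; between-specimen length spread dominates placement
  # error, so ICC(A,1) must exceed 0.9
  cohort <- generate_cohort(24, seed = 77)
  ratings <- t(vapply(seq_along(cohort), function(i) {
    vapply(1:2, function(rep) {
      ps <- generate_point_set(cohort[[i]], 100, px_per_cm = 40,
                               jitter_px = 2, seed = 1000 * i + rep)
      arc_length(ps, calibrate_scale(ps))
    }, numeric(1))
  }, numeric(2)))
  r <- icc_a1(ratings)
  expect_gt(r$icc, 0.9)
})
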