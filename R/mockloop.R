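#' Mock-circulatory-loop configuration
#'
#' Settings of the bench rig emulator: a pulsatile pump (half-sine
#' ventricular ejection) drives a three-element Windkessel afterload whose
#' peripheral resistance and compliance are auto-tuned so the zone-3
#' pressure hits physiologic baseline windows. Arch angulation (Type III)
#' is encoded as a peripheral-resistance factor plus a pressure-dependent
#' wall stiffening; a deployed stent-graft speeds the wave up over its
#' covered length.
#'
#' The arch-effect parameters are calibration knobs, not a mechanistic
#' claim: the rig literature hypothesizes an increased systemic vascular
#' resistance with angulation, and the defaults are calibrated so a Type III
#' mount raises MAP by roughly 8 mmHg and PWV by 8-9% over Type I.
#'
#' @param heart_rate Pump rate, beats/min.
#' @param cardiac_output_target Mean flow target, L/min (physiologic window
#'   4.5-5.5).
#' @param pressure_windows Named list of length-2 numeric ranges (mmHg) for
#'   `DBP`, `SBP`, `PP`, `MAP` that the tuned baseline must satisfy.
#' @param map_target,pp_target Tuning set-points in mmHg. `map_target`
#'   defaults to the MAP window center; `pp_target` sits slightly below the
#'   PP window center so the implied SBP (`MAP + 2/3 PP`) keeps headroom
#'   inside its own window.
#' @param R Peripheral resistance in Pa s/m^3; `NA` requests auto-tuning.
#' @param C Compliance in m^3/Pa; `NA` requests auto-tuning.
#' @param char_impedance_frac Characteristic impedance of the proximal
#'   Windkessel element, as a fraction of `R`.
#' @param ejection_fraction Fraction of the cycle occupied by ejection.
#' @param arch_type `"I"` or `"III"`.
#' @param arch_resistance_factor Multiplier (>= 1) applied to the tuned
#'   peripheral resistance when mounted in the Type III guide.
#' @param arch_stiffening_exponent Exponent linking wave speed to distending
#'   pressure, `c = c0 * (MAP / map_ref)^exponent`.
#' @param arch_effect_sd Log-normal SD of the per-specimen Type III
#'   stiffening response (0 disables heterogeneity).
#' @param arch_effect_factor Optional fixed stiffening-response multiplier
#'   for the mounted specimen; when `NA` a factor is drawn from
#'   `arch_effect_sd` using the acquisition seed. Study orchestration draws
#'   one factor per specimen so both of its Type III acquisitions share it.
#' @param arch_length_delta_cm Centerline length increase (cm) when mounted
#'   in the Type III guide.
#' @param map_ref Reference MAP (mmHg) at which the specimen wave speed
#'   equals its Moens-Korteweg value.
#' @param length_ref_pressure Pressure (mmHg) at which `length_ref` of the
#'   specimen is defined.
#' @param stent Logical; is a stent-graft deployed.
#' @param stent_covered_length_mm Covered length of the device, mm.
#' @param stent_speed_factor Local wave-speed multiplier (>= 1) over the
#'   covered segment; the default is calibrated to a ~7% PWV rise in a
#'   Type I mount.
#' @param distal_damping Fraction (0, 1] of the pulsatile component retained
#'   at the distal flow meter.
#' @param sampling_rate Hz (>= 100).
#' @param n_cycles Number of consecutive cardiac cycles acquired (>= 25).
#' @param noise_sd Additive Gaussian measurement noise, as a fraction of
#'   each waveform's peak-to-peak amplitude.
#' @param seed Integer seed for the acquisition's noise streams.
#' @return An object of class `mockloop_config`.
#' @export
mockloop_config <- function(heart_rate = 75,
                            cardiac_output_target = 5.0,
                            pressure_windows = list(
                              DBP = c(75, 85), SBP = c(115, 125),
                              PP = c(40, 50), MAP = c(90, 100)),
                            map_target = mean(pressure_windows$MAP),
                            pp_target = 41,
                            R = NA_real_, C = NA_real_,
                            char_impedance_frac = 0.05,
                            ejection_fraction = 0.35,
                            arch_type = c("I", "III"),
                            arch_resistance_factor = 1.085,
                            arch_stiffening_exponent = 1.0,
                            arch_effect_sd = 0.10,
                            arch_effect_factor = NA_real_,
                            arch_length_delta_cm = 0.7,
                            map_ref = 95,
                            length_ref_pressure = 100,
                            stent = FALSE,
                            stent_covered_length_mm = 112,
                            stent_speed_factor = 1.28,
                            distal_damping = 0.9,
                            sampling_rate = 1000,
                            n_cycles = 25,
                            noise_sd = 0.01,
                            seed = 1) {
  arch_type <- match.arg(arch_type)
  if (n_cycles < 25) stop("n_cycles must be at least 25")
  if (sampling_rate < 100) stop("sampling_rate must be at least 100 Hz")
  if (stent_speed_factor < 1) stop("stent_speed_factor must be >= 1")
  if (arch_resistance_factor < 1) stop("arch_resistance_factor must be >= 1")
  if (heart_rate <= 0 || cardiac_output_target <= 0)
    stop("heart_rate and cardiac_output_target must be positive")
  if (!all(c("DBP", "SBP", "PP", "MAP") %in% names(pressure_windows)))
    stop("pressure_windows must name DBP, SBP, PP and MAP")
  for (w in pressure_windows)
    if (length(w) != 2 || w[2] <= w[1])
      stop("each pressure window must be a non-empty (lo, hi) range")
  if (ejection_fraction <= 0 || ejection_fraction >= 1)
    stop("ejection_fraction must be in (0, 1)")
  if (distal_damping <= 0 || distal_damping > 1)
    stop("distal_damping must be in (0, 1]")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  structure(
    list(heart_rate = heart_rate,
         cardiac_output_target = cardiac_output_target,
         pressure_windows = pressure_windows,
         map_target = map_target, pp_target = pp_target,
         R = R, C = C, char_impedance_frac = char_impedance_frac,
         ejection_fraction = ejection_fraction,
         arch_type = arch_type,
         arch_resistance_factor = arch_resistance_factor,
         arch_stiffening_exponent = arch_stiffening_exponent,
         arch_effect_sd = arch_effect_sd,
         arch_effect_factor = arch_effect_factor,
         arch_length_delta_cm = arch_length_delta_cm,
         map_ref = map_ref, length_ref_pressure = length_ref_pressure,
         stent = stent,
         stent_covered_length_mm = stent_covered_length_mm,
         stent_speed_factor = stent_speed_factor,
         distal_damping = distal_damping,
         sampling_rate = sampling_rate, n_cycles = n_cycles,
         noise_sd = noise_sd, seed = seed),
    class = "mockloop_config"
  )
}

#' @export
print.mockloop_config <- function(x, ...) {
  cat(sprintf(
    "<mockloop_config> Type %s%s: %g bpm, CO %g L/min, %g Hz, %d cycles\n",
    x$arch_type, if (x$stent) " + stent" else "", x$heart_rate,
    x$cardiac_output_target, x$sampling_rate, x$n_cycles))
  cat(sprintf("  tuning targets: MAP %g, PP %g mmHg; noise %g%% p-p\n",
              x$map_target, x$pp_target, 100 * x$noise_sd))
  invisible(x)
}

# Closed-form periodic ventricular ejection flow (m^3/s): half-sine over the
# ejection window, zero in diastole, scaled to the requested mean output.
ejection_flow_fun <- function(co_m3s, cycle_s, ejection_fraction) {
  te <- ejection_fraction * cycle_s
  peak <- co_m3s * pi * cycle_s / (2 * te)
  function(t) {
    tt <- t %% cycle_s
    ifelse(tt < te, peak * sin(pi * tt / te), 0)
  }
}

# Periodic steady-state zone-3 pressure (mmHg) of a 3-element Windkessel
# driven by one sampled flow cycle (m^3/s): the proximal element Zc adds
# Zc*Q, the R-C pair filters each flow harmonic with impedance
# R / (1 + i w R C). Solved exactly in the frequency domain.
windkessel_pressure <- function(q_cycle, R, C, Zc, sampling_rate) {
  n <- length(q_cycle)
  cycle_s <- n / sampling_rate
  k <- 0:(n - 1)
  f <- ifelse(k <= n / 2, k, k - n) / cycle_s
  Z <- R / (1 + 1i * 2 * pi * f * R * C)
  p <- Re(stats::fft(stats::fft(q_cycle) * Z, inverse = TRUE)) / n +
    Zc * q_cycle
  pa_to_mmhg(p)
}

cycle_pressure_stats <- function(p_cycle) {
  dbp <- min(p_cycle); sbp <- max(p_cycle)
  pp <- sbp - dbp
  c(DBP = dbp, SBP = sbp, PP = pp, MAP = dbp + pp / 3)
}

#' Auto-tune the Windkessel afterload
#'
#' Mirrors the experimenters' knob-setting: bisection on peripheral
#' resistance `R` until the measured MAP hits `map_target`, then bisection
#' on compliance `C` until the pulse pressure hits `pp_target`; the two
#' sweeps are repeated because each knob perturbs the other's target. The
#' tuned baseline must land every pressure inside its configured window,
#' otherwise an error names the first unmet window.
#'
#' @param config A [mockloop_config()]; tuning always runs at the baseline
#'   (Type I, resistance factor 1) settings.
#' @param max_iter Bisection iterations per knob per sweep (<= 50).
#' @return List with elements `R` (Pa s/m^3), `C` (m^3/Pa) and `pressures`
#'   (named DBP/SBP/PP/MAP vector of the tuned noise-free baseline).
#' @export
tune_windkessel <- function(config, max_iter = 40) {
  stopifnot(inherits(config, "mockloop_config"), max_iter <= 50)
  fs <- config$sampling_rate
  cycle_s <- 60 / config$heart_rate
  n <- round(fs * cycle_s)
  qf <- ejection_flow_fun(lmin_to_m3s(config$cardiac_output_target),
                          cycle_s, config$ejection_fraction)
  q <- qf((0:(n - 1)) / fs)
  zc_f <- config$char_impedance_frac
  measure <- function(R, C)
    cycle_pressure_stats(windkessel_pressure(q, R, C, zc_f * R, fs))
  R <- 1.5e8; C <- 1.2e-8
  for (sweep in 1:2) {
    lo <- 1e7; hi <- 1e9
    for (i in seq_len(max_iter)) {
      R <- sqrt(lo * hi)
      if (measure(R, C)[["MAP"]] < config$map_target) lo <- R else hi <- R
    }
    lo <- 1e-10; hi <- 1e-6
    for (i in seq_len(max_iter)) {
      C <- sqrt(lo * hi)
      if (measure(R, C)[["PP"]] > config$pp_target) lo <- C else hi <- C
    }
  }
  p <- measure(R, C)
  for (nm in c("DBP", "SBP", "PP", "MAP")) {
    w <- config$pressure_windows[[nm]]
    if (p[[nm]] < w[1] || p[[nm]] > w[2])
      stop(sprintf(
        "windkessel tuning failed: %s = %.1f mmHg outside window [%g, %g]",
        nm, p[[nm]], w[1], w[2]))
  }
  list(R = R, C = C, pressures = p)
}

#' Simulate a paired proximal/distal flow acquisition
#'
#' Generates the proximal ejection flow and a distal flow equal to the
#' proximal waveform delayed by an imposed transit time (evaluated in closed
#' form, so fractional-sample delays are exact) with its pulsatile component
#' damped, plus additive Gaussian measurement noise.
#'
#' @param config A [mockloop_config()].
#' @param transit_time Imposed proximal-to-distal delay in seconds.
#' @return List with `proximal` and `distal` [waveform_record()]s (L/min).
#' @export
simulate_flow_pair <- function(config, transit_time) {
  stopifnot(inherits(config, "mockloop_config"), transit_time >= 0)
  cycle_s <- 60 / config$heart_rate
  if (transit_time >= cycle_s / 2)
    stop("transit_time must be below half a cardiac cycle")
  fs <- config$sampling_rate
  n <- round(fs * cycle_s) * config$n_cycles
  t <- (0:(n - 1)) / fs
  co <- lmin_to_m3s(config$cardiac_output_target)
  qf <- ejection_flow_fun(co, cycle_s, config$ejection_fraction)
  qp <- m3s_to_lmin(qf(t))
  qd <- mean(qp) + config$distal_damping * (m3s_to_lmin(qf(t - transit_time)) -
                                              mean(qp))
  ptp <- diff(range(qp))
  if (config$noise_sd > 0) {
    qp <- qp + with_seed(substream_seed(config$seed, 1),
                         stats::rnorm(n, 0, config$noise_sd * ptp))
    qd <- qd + with_seed(substream_seed(config$seed, 2),
                         stats::rnorm(n, 0, config$noise_sd * ptp))
  }
  list(
    proximal = waveform_record(qp, fs, "proximal", "flow", config$heart_rate),
    distal = waveform_record(qd, fs, "distal", "flow", config$heart_rate)
  )
}

#' Simulate one bench acquisition of an aortic sample
#'
#' Full forward model of a mock-loop acquisition: the Windkessel is tuned
#' (or reuses supplied `R`, `C`) at baseline settings; a Type III mount
#' multiplies the peripheral resistance; the specimen's wave speed is its
#' Moens-Korteweg value at point 2 scaled by the pressure-stiffening term
#' `(MAP / map_ref)^exponent` (plus optional per-specimen Type III
#' heterogeneity); centerline length is evaluated at the realized MAP; a
#' deployed stent-graft speeds the wave over its covered 112 mm so the true
#' transit time is `(L - Ls)/c + Ls/(kappa c)`. The returned ground truth
#' supports recovery testing of the estimation pipeline.
#'
#' @param sample An [aorta_sample()].
#' @param config A [mockloop_config()].
#' @return List with `proximal`, `distal`, `zone3` [waveform_record()]s and
#'   a `truth` list (`true_wave_speed` m/s, `true_transit_time` s,
#'   `true_length_at_map_cm`, `map_mmhg`, `R`, `C`).
#' @examples
#' s <- aorta_sample("demo", 25.4, 22.8, 16.3, 14.6, length_ref = 36.2)
#' acq <- simulate_sample(s, mockloop_config(noise_sd = 0))
#' acq$truth$true_wave_speed
#' @export
simulate_sample <- function(sample, config) {
  stopifnot(inherits(sample, "aorta_sample"),
            inherits(config, "mockloop_config"))
  fs <- config$sampling_rate
  cycle_s <- 60 / config$heart_rate
  n_cyc <- round(fs * cycle_s)

  if (is.finite(config$R) && is.finite(config$C)) {
    tuned <- list(R = config$R, C = config$C)
  } else {
    tuned <- tune_windkessel(config)
  }
  fac <- if (config$arch_type == "III") config$arch_resistance_factor else 1
  R_eff <- tuned$R * fac
  qf <- ejection_flow_fun(lmin_to_m3s(config$cardiac_output_target),
                          cycle_s, config$ejection_fraction)
  q_cycle <- qf((0:(n_cyc - 1)) / fs)
  p_cycle <- windkessel_pressure(q_cycle, R_eff, tuned$C,
                                 config$char_impedance_frac * R_eff, fs)
  pstats <- cycle_pressure_stats(p_cycle)
  map <- pstats[["MAP"]]

  c0 <- moens_korteweg(sample$E, sample$h, sample$d2 / 2000, sample$rho)
  stiff <- (map / config$map_ref)^config$arch_stiffening_exponent
  hetero <- 1
  if (config$arch_type == "III") {
    if (is.finite(config$arch_effect_factor)) {
      hetero <- config$arch_effect_factor
    } else if (config$arch_effect_sd > 0) {
      hetero <- exp(with_seed(substream_seed(config$seed, 9),
                              stats::rnorm(1, 0, config$arch_effect_sd)))
    }
  }
  c_eff <- c0 * stiff * hetero

  delta <- if (config$arch_type == "III") config$arch_length_delta_cm else 0
  L_cm <- sample$length_ref + delta +
    sample$length_slope * (map - config$length_ref_pressure)
  L_m <- L_cm / 100
  if (config$stent) {
    Ls <- min(config$stent_covered_length_mm / 1000, L_m)
    tt <- (L_m - Ls) / c_eff + Ls / (config$stent_speed_factor * c_eff)
  } else {
    tt <- L_m / c_eff
  }

  flows <- simulate_flow_pair(config, tt)
  p_all <- rep(p_cycle, config$n_cycles)
  if (config$noise_sd > 0) {
    p_all <- p_all + with_seed(substream_seed(config$seed, 3),
                               stats::rnorm(length(p_all), 0,
                                            config$noise_sd *
                                              diff(range(p_cycle))))
  }
  zone3 <- waveform_record(p_all, fs, "zone3", "pressure", config$heart_rate)

  list(proximal = flows$proximal, distal = flows$distal, zone3 = zone3,
       truth = list(true_wave_speed = c_eff, true_transit_time = tt,
                    true_length_at_map_cm = L_cm, map_mmhg = map,
                    R = tuned$R, C = tuned$C))
}
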