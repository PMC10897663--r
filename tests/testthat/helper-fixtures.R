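# Shared fixtures: a reference specimen, periodic smooth-pulse pairs with
# exact fractional delays, and independent oracles used across test files.

ref_sample <- function(length_ref = 36.2, length_slope = 0.01, ...) {
  aorta_sample("REF", 25.4, 22.8, 16.3, 14.6, length_ref = length_ref,
               length_slope = length_slope, ...)
}

# Specimen whose Moens-Korteweg wave speed at point 2 is exactly `c_ms`.
sample_with_speed <- function(c_ms, length_ref = 36.2, h = 2e-3,
                              rho = 1000) {
  r2 <- 22.8 / 2000
  aorta_sample(sprintf("C%.1f", c_ms), 25.4, 22.8, 16.3, 14.6,
               length_ref = length_ref, E = 2 * rho * r2 * c_ms^2 / h,
               h = h, rho = rho)
}

# Periodic smooth pulse (Gaussian bump per cycle) sampled at fs, delayed by
# an exact fractional amount via closed-form evaluation.
pulse_pair <- function(delay_s, fs = 1000, hr = 75, n_cycles = 25,
                       noise_sd = 0, seed = 1, width_frac = 0.08) {
  cycle_s <- 60 / hr
  n <- round(fs * cycle_s) * n_cycles
  t <- (0:(n - 1)) / fs
  f <- function(t) {
    ph <- (t %% cycle_s) / cycle_s
    exp(-((ph - 0.3) / width_frac)^2)
  }
  x <- f(t)
  y <- f(t - delay_s)
  if (noise_sd > 0) {
    set.seed(seed)
    x <- x + rnorm(n, 0, noise_sd)
    y <- y + rnorm(n, 0, noise_sd)
  }
  list(
    prox = waveform_record(x, fs, "proximal", "flow", hr),
    dist = waveform_record(y, fs, "distal", "flow", hr)
  )
}

# Independent delay oracle: dense integer-lag circular cross-correlation of
# the pair regenerated on a 10x finer grid (no parabolic refinement).
oracle_delay <- function(delay_s, fs = 1000, hr = 75, width_frac = 0.08) {
  fine <- 10 * fs
  cycle_s <- 60 / hr
  n <- round(fine * cycle_s)
  t <- (0:(n - 1)) / fine
  f <- function(t) {
    ph <- (t %% cycle_s) / cycle_s
    exp(-((ph - 0.3) / width_frac)^2)
  }
  x <- f(t) - mean(f(t))
  y <- f(t - delay_s) - mean(f(t - delay_s))
  cc <- Re(fft(Conj(fft(x)) * fft(y), inverse = TRUE))
  lags <- 1:floor(n / 2)
  lags[which.max(cc[lags + 1])] / fine
}

# Independent ICC(A,1) oracle: mean squares from a two-way aov fit.
icc_aov_oracle <- function(m) {
  n <- nrow(m); k <- ncol(m)
  d <- data.frame(y = as.vector(m), subj = factor(rep(seq_len(n), k)),
                  rater = factor(rep(seq_len(k), each = n)))
  av <- stats::anova(stats::aov(y ~ subj + rater, data = d))
  MSR <- av["subj", "Mean Sq"]; MSC <- av["rater", "Mean Sq"]
  MSE <- av["Residuals", "Mean Sq"]
  (MSR - MSE) / (MSR + (k - 1) * MSE + k * (MSC - MSE) / n)
}

# Loop configuration with arch and stent effects switched off entirely.
null_effects_config <- function(...) {
  mockloop_config(arch_resistance_factor = 1, arch_stiffening_exponent = 0,
                  arch_effect_sd = 0, arch_length_delta_cm = 0,
                  noise_sd = 0, ...)
}
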