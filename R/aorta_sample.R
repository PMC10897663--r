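#' Moens-Korteweg wave speed
#'
#' Pulse wave speed in a thin-walled elastic tube,
#' `c = sqrt(E * h / (2 * rho * r))`, where `E` is the wall Young modulus,
#' `h` the wall thickness, `r` the lumen radius and `rho` the fluid density.
#' This ties the simulated transit times to an explicit wall-mechanics model
#' instead of an arbitrary delay.
#'
#' @param E Wall elastic (Young) modulus in Pa.
#' @param h Wall thickness in m.
#' @param r Lumen radius in m.
#' @param rho Fluid density in kg/m^3 (water, the circulatory fluid of the
#'   bench rig, is 1000).
#' @return Wave speed in m/s.
#' @examples
#' moens_korteweg(E = 400e3, h = 2e-3, r = 11.4e-3, rho = 1000) # ~5.92 m/s
#' @export
moens_korteweg <- function(E, h, r, rho = 1000) {
  if (any(c(E, h, r, rho) <= 0) || any(!is.finite(c(E, h, r, rho))))
    stop("moens_korteweg: all arguments must be positive and finite")
  sqrt(E * h / (2 * rho * r))
}

#' Aortic specimen description
#'
#' One thoracic aortic sample: lumen diameters at the four standard
#' measurement points (1: ascending aorta, 2: proximal landing zone just
#' distal to the second supra-aortic trunk, 3: distal landing zone 112 mm
#' further, 4: distal descending aorta), a pressure-dependent centerline
#' length model, and the wall parameters that set its Moens-Korteweg wave
#' speed.
#'
#' Diameters must taper (`d1 > d2 > d3 > d4`), mirroring the proximal-to-
#' distal narrowing of the thoracic aorta.
#'
#' @param sample_id Identifier string.
#' @param d1,d2,d3,d4 Diameters in mm at measurement points 1-4.
#' @param length_ref Centerline length in cm at the reference pressure
#'   (100 mmHg continuous flow).
#' @param length_slope Length increase in cm per mmHg of distending pressure.
#' @param E Wall elastic modulus in Pa; the default yields a baseline wave
#'   speed near 3.5 m/s at the point-2 radius, typical of young porcine
#'   thoracic aortas.
#' @param h Wall thickness in m.
#' @param rho Fluid density in kg/m^3.
#' @return An object of class `aorta_sample`.
#' @export
aorta_sample <- function(sample_id, d1, d2, d3, d4, length_ref,
                         length_slope = 0.01, E = 142e3, h = 2e-3,
                         rho = 1000) {
  d <- c(d1, d2, d3, d4)
  if (any(!is.finite(d)) || any(d <= 0))
    stop("diameters must be positive and finite")
  if (!(d1 > d2 && d2 > d3 && d3 > d4))
    stop("diameters must taper: d1 > d2 > d3 > d4")
  if (length_ref <= 0) stop("length_ref must be positive")
  if (length_slope < 0) stop("length_slope must be non-negative")
  if (any(c(E, h, rho) <= 0)) stop("E, h and rho must be positive")
  structure(
    list(sample_id = as.character(sample_id), d1 = d1, d2 = d2, d3 = d3,
         d4 = d4, length_ref = length_ref, length_slope = length_slope,
         E = E, h = h, rho = rho),
    class = "aorta_sample"
  )
}

#' @export
print.aorta_sample <- function(x, ...) {
  cat(sprintf("<aorta_sample> %s\n", x$sample_id))
  cat(sprintf("  diameters (mm): %.1f / %.1f / %.1f / %.1f\n",
              x$d1, x$d2, x$d3, x$d4))
  cat(sprintf("  length %.1f cm @100 mmHg (+%.3f cm/mmHg)\n",
              x$length_ref, x$length_slope))
  cat(sprintf("  wall: E = %.0f kPa, h = %.2f mm -> c0 = %.2f m/s\n",
              x$E / 1e3, x$h * 1e3,
              moens_korteweg(x$E, x$h, x$d2 / 2000, x$rho)))
  invisible(x)
}

#' Population parameters for cohort generation
#'
#' Defaults describe the tapering geometry of young porcine thoracic aortas
#' (means and SDs of the four diameters and the Type I centerline length)
#' together with a target baseline wave-speed distribution. Wall modulus is
#' back-solved per specimen from its drawn wave speed and point-2 radius via
#' [moens_korteweg()], so the simulated PWV distribution is controlled
#' directly.
#'
#' @param d_mean,d_sd Length-4 vectors: mean and SD of diameters (mm) at the
#'   four measurement points.
#' @param length_mean,length_sd Mean and SD of centerline length (cm) at
#'   100 mmHg in the Type I configuration.
#' @param length_slope_mean,length_slope_sd Mean and SD of the length
#'   sensitivity to pressure (cm/mmHg).
#' @param wave_speed_mean,wave_speed_sd Mean and SD of the baseline
#'   (Type I) wave speed in m/s.
#' @param wall_thickness Wall thickness in m (common to the cohort).
#' @param rho Fluid density in kg/m^3.
#' @return A list of population parameters.
#' @export
cohort_population <- function(d_mean = c(25.4, 22.8, 16.3, 14.6),
                              d_sd = c(1.8, 1.6, 1.0, 1.3),
                              length_mean = 36.2, length_sd = 2.6,
                              length_slope_mean = 0.010,
                              length_slope_sd = 0.002,
                              wave_speed_mean = 3.53, wave_speed_sd = 0.40,
                              wall_thickness = 2e-3, rho = 1000) {
  stopifnot(length(d_mean) == 4, length(d_sd) == 4,
            all(d_sd >= 0), all(d_mean > 0),
            length_mean > 0, length_sd >= 0,
            wave_speed_mean > 0, wave_speed_sd >= 0,
            wall_thickness > 0, rho > 0)
  list(d_mean = d_mean, d_sd = d_sd,
       length_mean = length_mean, length_sd = length_sd,
       length_slope_mean = length_slope_mean,
       length_slope_sd = length_slope_sd,
       wave_speed_mean = wave_speed_mean, wave_speed_sd = wave_speed_sd,
       wall_thickness = wall_thickness, rho = rho)
}

# Truncated-normal draw by rejection; bounds at mean +- 3.5 SD clipped to
# (lo_floor, Inf) keep values physiological without visibly distorting the
# distribution.
rtrunc_norm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  if (sd == 0) return(rep(mean, n))
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      x <- stats::rnorm(1, mean, sd)
      if (x >= lo && x <= hi) break
    }
    out[i] <- x
  }
  out
}

#' Generate a synthetic cohort of aortic samples
#'
#' Draws `n` specimens from independent truncated normals for the four
#' diameters (re-drawn until the tapering order `d1 > d2 > d3 > d4` holds),
#' the centerline length, the pressure-length slope and the baseline wave
#' speed; each specimen's wall modulus is back-solved from its wave speed.
#'
#' @param n Number of specimens (>= 1).
#' @param population Parameters from [cohort_population()].
#' @param seed Integer seed; fixed seed gives an identical cohort.
#' @return List of [aorta_sample()] objects.
#' @examples
#' cohort <- generate_cohort(5, seed = 42)
#' sapply(cohort, function(s) s$d2)
#' @export
generate_cohort <- function(n, population = cohort_population(), seed = 1) {
  if (!is.numeric(n) || n < 1) stop("n must be a positive integer")
  n <- as.integer(n)
  p <- population
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      repeat {
        d <- mapply(function(m, s) {
          rtrunc_norm(1, m, s, lo = max(1, m - 3.5 * s), hi = m + 3.5 * s)
        }, p$d_mean, p$d_sd)
        if (d[1] > d[2] && d[2] > d[3] && d[3] > d[4]) break
      }
      len <- rtrunc_norm(1, p$length_mean, p$length_sd,
                         lo = max(10, p$length_mean - 3.5 * p$length_sd),
                         hi = p$length_mean + 3.5 * p$length_sd)
      slope <- rtrunc_norm(1, p$length_slope_mean, p$length_slope_sd,
                           lo = 0, hi = p$length_slope_mean +
                             3.5 * p$length_slope_sd)
      c_target <- rtrunc_norm(1, p$wave_speed_mean, p$wave_speed_sd,
                              lo = max(1, p$wave_speed_mean -
                                         3.5 * p$wave_speed_sd),
                              hi = p$wave_speed_mean +
                                3.5 * p$wave_speed_sd)
      r2 <- d[2] / 2000 # mm -> m radius at the proximal landing zone
      E <- 2 * p$rho * r2 * c_target^2 / p$wall_thickness
      aorta_sample(sprintf("S%03d", i), d[1], d[2], d[3], d[4],
                   length_ref = len, length_slope = slope,
                   E = E, h = p$wall_thickness, rho = p$rho)
    })
  })
}
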