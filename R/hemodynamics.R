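#' Compute pulse wave velocity
#'
#' PWV is the calibrated centerline length divided by the proximal-to-distal
#' transit time. The field reports PWV to 0.01 m/s; the stored value keeps
#' full precision and the print method rounds.
#'
#' @param length_m Centerline length in m (length at the pulsatile-flow MAP).
#' @param transit_time Transit time in s.
#' @param configuration Optional label, e.g. `"TypeI_native"`.
#' @return An object of class `pwv_result` with fields `pwv` (m/s),
#'   `transit_time`, `length_m`, `configuration`.
#' @examples
#' compute_pwv(0.362, 0.1025) # 3.53 m/s
#' @export
compute_pwv <- function(length_m, transit_time, configuration = NA_character_) {
  if (!is.finite(length_m) || length_m <= 0)
    stop("length_m must be positive")
  if (!is.finite(transit_time) || transit_time <= 0)
    stop("non-positive transit time: upstream correlation failed")
  structure(
    list(pwv = length_m / transit_time, transit_time = transit_time,
         length_m = length_m, configuration = configuration),
    class = "pwv_result")
}

#' @export
print.pwv_result <- function(x, ...) {
  cat(sprintf("<pwv_result> PWV = %.2f m/s (L = %.3f m, TT = %.4f s)%s\n",
              x$pwv, x$length_m, x$transit_time,
              if (is.na(x$configuration)) "" else
                paste0(" [", x$configuration, "]")))
  invisible(x)
}

#' Stent-graft oversizing fraction
#'
#' Fractional excess of the stent-graft diameter over the aortic diameter
#' at the landing zone: `d_graft / d_aorta - 1`. This denominator
#' convention is the one under which a 26 mm device on a 22.8 mm landing
#' zone gives 14% and the 10-20% eligibility window inverts to
#' 21.7-23.6 mm.
#'
#' @param d_graft Stent-graft diameter in mm.
#' @param d_aorta Aortic diameter at the landing zone in mm.
#' @return Dimensionless oversizing fraction (0.14 means 14%).
#' @examples
#' oversizing_fraction(26, 22.8)
#' @export
oversizing_fraction <- function(d_graft, d_aorta) {
  if (any(!is.finite(c(d_graft, d_aorta))) || d_graft <= 0 || d_aorta <= 0)
    stop("diameters must be positive")
  d_graft / d_aorta - 1
}

#' Aortic-diameter eligibility range for a target oversizing window
#'
#' Inverts the oversizing rule: a device of diameter `d_graft` achieves an
#' oversizing between `lo` and `hi` exactly when the landing-zone diameter
#' lies in `[d_graft/(1+hi), d_graft/(1+lo)]`. Bounds are reported to
#' 0.1 mm (the operational precision of the caliper rule) and membership is
#' inclusive.
#'
#' @param d_graft Stent-graft diameter in mm.
#' @param lo,hi Oversizing window as fractions (`0 <= lo < hi`).
#' @return Named numeric vector `c(d_min, d_max)` in mm, rounded to 0.1 mm.
#' @examples
#' eligibility_range(26, 0.10, 0.20) # 21.7 - 23.6 mm
#' @export
eligibility_range <- function(d_graft, lo = 0.10, hi = 0.20) {
  if (!is.finite(d_graft) || d_graft <= 0) stop("d_graft must be positive")
  if (lo < 0 || lo >= hi) stop("need 0 <= lo < hi")
  c(d_min = round(d_graft / (1 + hi), 1),
    d_max = round(d_graft / (1 + lo), 1))
}

#' Percent change between paired measurements
#'
#' `100 * (after - before) / before`. Note that the mean of per-sample
#' percent changes and the percent change of the means are different
#' estimands; cohort summaries report both.
#'
#' @param before,after Paired values; `before` must be positive.
#' @return Percent change.
#' @examples
#' percent_change(3.55, 3.81) # 7.3
#' @export
percent_change <- function(before, after) {
  if (any(!is.finite(c(before, after))) || any(before <= 0))
    stop("before must be positive and finite")
  100 * (after - before) / before
}
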