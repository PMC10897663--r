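#' Planar point set along the aortic centerline
#'
#' Ordered pixel coordinates placed proximal-to-distal on a planar image of
#' the mounted aorta, plus the endpoints of the 2.5 cm reference line
#' printed on the arch guide, tagged with the continuous-flow acquisition
#' pressure.
#'
#' @param points Two-column numeric matrix (or data.frame) of ordered
#'   `(x_px, y_px)` coordinates; at least 15 points.
#' @param scale_segment 2x2 matrix: pixel endpoints of the 2.5 cm reference
#'   line.
#' @param pressure Acquisition pressure in mmHg (continuous-flow levels are
#'   80, 100 and 120).
#' @return An object of class `planar_point_set`.
#' @export
planar_point_set <- function(points, scale_segment, pressure) {
  points <- as.matrix(points)
  if (ncol(points) != 2) stop("points must have two columns (x_px, y_px)")
  if (nrow(points) < 15)
    stop("a minimum of 15 points must be placed along the centerline")
  if (!all(is.finite(points))) stop("point coordinates must be finite")
  scale_segment <- as.matrix(scale_segment)
  if (!all(dim(scale_segment) == c(2, 2)))
    stop("scale_segment must be a 2x2 matrix of pixel endpoints")
  if (sqrt(sum((scale_segment[2, ] - scale_segment[1, ])^2)) <= 0)
    stop("scale segment endpoints must not coincide")
  if (pressure <= 0) stop("pressure must be positive")
  structure(list(points = points, scale_segment = scale_segment,
                 pressure = pressure),
            class = "planar_point_set")
}

#' @export
print.planar_point_set <- function(x, ...) {
  cat(sprintf("<planar_point_set> %d points at %g mmHg (scale line %.1f px)\n",
              nrow(x$points), x$pressure,
              sqrt(sum((x$scale_segment[2, ] - x$scale_segment[1, ])^2))))
  invisible(x)
}

#' Pixel-to-centimeter scale calibration
#'
#' The 2.5 cm reference line on the arch guide sets the conversion:
#' `cm_per_px = 2.5 / pixel_length(scale_segment)`.
#'
#' @param point_set A [planar_point_set()].
#' @param reference_cm Physical length of the reference line in cm.
#' @return Scale factor in cm per pixel.
#' @export
calibrate_scale <- function(point_set, reference_cm = 2.5) {
  stopifnot(inherits(point_set, "planar_point_set"))
  px <- sqrt(sum((point_set$scale_segment[2, ] -
                    point_set$scale_segment[1, ])^2))
  if (px <= 0) stop("degenerate scale segment")
  reference_cm / px
}

#' Calibrated polyline arc length
#'
#' Sum of consecutive Euclidean point distances times the pixel scale.
#' The polyline rule keeps the measurement reproducible from manually
#' placed points and its chord-sum error against a smooth underlying curve
#' is bounded and testable; zero-length segments from duplicate consecutive
#' points are allowed and contribute nothing.
#'
#' @param point_set A [planar_point_set()].
#' @param cm_per_px Scale from [calibrate_scale()].
#' @param min_points Minimum number of points required.
#' @return Centerline length in cm.
#' @export
arc_length <- function(point_set, cm_per_px = calibrate_scale(point_set),
                       min_points = 15) {
  stopifnot(inherits(point_set, "planar_point_set"))
  p <- point_set$points
  if (nrow(p) < min_points)
    stop(sprintf("at least %d points required", min_points))
  d <- sqrt(rowSums((p[-1, , drop = FALSE] -
                       p[-nrow(p), , drop = FALSE])^2))
  sum(d) * cm_per_px
}

#' Fit the pressure-length regression
#'
#' Ordinary least squares of centerline length (cm) on distending pressure
#' (mmHg) across the continuous-flow acquisitions; the fitted line supplies
#' the length at the MAP realized during pulsatile flow, which is the
#' length entering PWV.
#'
#' @param pressures Pressures in mmHg (at least two distinct values).
#' @param lengths Calibrated lengths in cm, one per pressure.
#' @return An object of class `length_fit` with fields `slope` (cm/mmHg),
#'   `intercept` (cm), `pressures`, `lengths`.
#' @examples
#' fit <- fit_length_pressure(c(80, 100, 120), c(36.0, 36.2, 36.4))
#' length_at(fit, 98)
#' @export
fit_length_pressure <- function(pressures, lengths) {
  stopifnot(is.numeric(pressures), is.numeric(lengths),
            length(pressures) == length(lengths), length(pressures) >= 2)
  if (length(unique(pressures)) < 2)
    stop("singular fit: at least two distinct pressures required")
  fit <- stats::lm(lengths ~ pressures)
  structure(
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         pressures = pressures, lengths = lengths),
    class = "length_fit")
}

#' Evaluate a pressure-length fit
#'
#' @param fit A `length_fit` from [fit_length_pressure()].
#' @param pressure Pressure in mmHg.
#' @return Predicted centerline length in cm.
#' @export
length_at <- function(fit, pressure) {
  stopifnot(inherits(fit, "length_fit"))
  fit$intercept + fit$slope * pressure
}

#' @export
print.length_fit <- function(x, ...) {
  cat(sprintf(
    "<length_fit> length = %.2f + %.4f * P cm (n = %d pressures)\n",
    x$intercept, x$slope, length(x$pressures)))
  invisible(x)
}

#' Generate a synthetic planar point set
#'
#' Synthetic stand-in for operator point placement on a digital planar
#' image: points are laid out along an arch-shaped curve (semicircular arch
#' continued by a straight descending limb), rescaled so the noise-free
#' polyline length equals the specimen's centerline length at the requested
#' pressure, converted to pixels, and jittered by independent Gaussian
#' pixel noise emulating manual clicking. The 2.5 cm reference line is
#' emitted un-jittered.
#'
#' @param sample An [aorta_sample()].
#' @param pressure Acquisition pressure in mmHg.
#' @param px_per_cm Image resolution in pixels per cm.
#' @param jitter_px SD of the Gaussian placement jitter in pixels.
#' @param n_points Number of placed points (>= 15).
#' @param seed Integer seed for the jitter stream.
#' @param arch_delta_cm Extra centerline length (cm) of the mounted arch
#'   configuration (0 for Type I, the configured delta for Type III).
#' @param ref_pressure Pressure at which `sample$length_ref` is defined.
#' @return A [planar_point_set()].
#' @export
generate_point_set <- function(sample, pressure, px_per_cm = 40,
                               jitter_px = 0, n_points = 16, seed = 1,
                               arch_delta_cm = 0, ref_pressure = 100) {
  stopifnot(inherits(sample, "aorta_sample"), pressure > 0, px_per_cm > 0,
            jitter_px >= 0)
  if (n_points < 15)
    stop("a minimum of 15 points must be placed along the centerline")
  target_cm <- sample$length_ref + arch_delta_cm +
    sample$length_slope * (pressure - ref_pressure)
  # arch-shaped base curve: semicircle of radius r then straight limb 2r,
  # parameterized by arc length; r set so total base length ~ target
  r <- target_cm / (pi + 2)
  s <- seq(0, (pi + 2) * r, length.out = n_points)
  xy <- t(vapply(s, function(si) {
    if (si <= pi * r) {
      th <- pi - si / r # sweep the arch from left to right
      c(r * cos(th), r * sin(th))
    } else {
      c(r, -(si - pi * r))
    }
  }, numeric(2)))
  # rescale so the polyline (chord-sum) length is exactly the target
  seg <- sqrt(rowSums((xy[-1, , drop = FALSE] -
                         xy[-n_points, , drop = FALSE])^2))
  xy <- xy * (target_cm / sum(seg))
  pts <- xy * px_per_cm
  pts[, 1] <- pts[, 1] + 2 * px_per_cm * r # keep coordinates positive
  pts[, 2] <- -pts[, 2] + 2 * px_per_cm * r # image y grows downward
  if (jitter_px > 0) {
    pts <- pts + with_seed(seed,
                           matrix(stats::rnorm(2 * n_points, 0, jitter_px),
                                  ncol = 2))
  }
  scale_seg <- rbind(c(5, 5), c(5 + 2.5 * px_per_cm, 5))
  planar_point_set(pts, scale_seg, pressure)
}
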