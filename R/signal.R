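#' Segment a waveform into cardiac cycles
#'
#' Cuts a record into consecutive complete cycles synchronized with the
#' pump rate; a partial trailing cycle is discarded. Acquisitions shorter
#' than `min_cycles` complete cycles are rejected, mirroring the protocol
#' requirement of at least 25 consecutive cycles per acquisition.
#'
#' @param record A [waveform_record()].
#' @param min_cycles Minimum number of complete cycles required.
#' @return An object of class `cycle_ensemble`: a list with `cycles`
#'   (matrix, one row per cycle), `heart_rate` and `sampling_rate`.
#' @export
segment_cycles <- function(record, min_cycles = 25) {
  stopifnot(inherits(record, "waveform_record"))
  spc <- round(record$sampling_rate * 60 / record$heart_rate)
  n_complete <- floor(length(record$values) / spc)
  if (n_complete < min_cycles)
    stop(sprintf(
      "insufficient data: %d complete cycles, %d required", n_complete,
      min_cycles))
  m <- matrix(record$values[seq_len(n_complete * spc)], nrow = n_complete,
              ncol = spc, byrow = TRUE)
  structure(list(cycles = m, heart_rate = record$heart_rate,
                 sampling_rate = record$sampling_rate),
            class = "cycle_ensemble")
}

#' @export
print.cycle_ensemble <- function(x, ...) {
  cat(sprintf("<cycle_ensemble> %d cycles x %d samples (%g bpm @ %g Hz)\n",
              nrow(x$cycles), ncol(x$cycles), x$heart_rate,
              x$sampling_rate))
  invisible(x)
}

#' Ensemble-average an ensemble of cardiac cycles
#'
#' Pointwise mean across cycles; with independent additive noise of SD
#' `sigma` per sample, the averaged cycle's residual noise is
#' `sigma / sqrt(n_cycles)`.
#'
#' @param ensemble A `cycle_ensemble` from [segment_cycles()].
#' @return Numeric vector: the averaged single cycle.
#' @export
ensemble_average <- function(ensemble) {
  stopifnot(inherits(ensemble, "cycle_ensemble"))
  if (nrow(ensemble$cycles) < 1) stop("empty ensemble")
  colMeans(ensemble$cycles)
}

# Circular normalized cross-correlation of two mean-subtracted cycles.
# Operating on the periodic single cycle is equivalent to tiling the cycle
# once and sliding with full overlap, so no edge samples are lost.
circular_xcorr <- function(x, y) {
  x <- x - mean(x); y <- y - mean(y)
  n <- length(x)
  cc <- Re(stats::fft(Conj(stats::fft(x)) * stats::fft(y),
                      inverse = TRUE)) / n # lag-k circular cross products
  denom <- sqrt(sum(x^2) * sum(y^2))
  if (denom == 0) return(rep(NA_real_, n))
  cc / denom
}

#' Estimate pulse transit time by cross-correlation
#'
#' Both flow records are segmented into cardiac cycles and ensemble
#' averaged; the delay is the lag maximizing the normalized circular
#' cross-correlation of the mean-subtracted averaged cycles, searched over
#' `(0, cycle/2]` and refined to sub-sample precision by three-point
#' parabolic interpolation around the integer-lag peak. Ties between equal
#' peaks resolve to the smallest (most physiological) lag. Identical inputs
#' return a zero transit time flagged as degenerate rather than an error.
#'
#' @param prox,dist Proximal and distal flow [waveform_record()]s with
#'   matching sampling and heart rates.
#' @param min_cycles Minimum complete cycles required of each record.
#' @param corr_floor Minimum acceptable peak correlation; below it the
#'   estimate is deemed unreliable and an error is raised.
#' @return An object of class `transit_time_result` with fields
#'   `transit_time` (s), `peak_correlation`, `lag_search_bounds` (s),
#'   `degenerate`.
#' @examples
#' cfg <- mockloop_config(noise_sd = 0)
#' pair <- simulate_flow_pair(cfg, transit_time = 0.1)
#' estimate_transit_time(pair$proximal, pair$distal)$transit_time
#' @export
estimate_transit_time <- function(prox, dist, min_cycles = 25,
                                  corr_floor = 0.5) {
  stopifnot(inherits(prox, "waveform_record"),
            inherits(dist, "waveform_record"))
  if (prox$sampling_rate != dist$sampling_rate)
    stop("sampling rates differ between records")
  if (prox$heart_rate != dist$heart_rate)
    stop("heart rates differ between records")
  x <- ensemble_average(segment_cycles(prox, min_cycles))
  y <- ensemble_average(segment_cycles(dist, min_cycles))
  n <- length(x)
  fs <- prox$sampling_rate
  cc <- circular_xcorr(x, y)
  if (all(is.na(cc))) stop("constant waveform: correlation undefined")
  k_max <- floor(n / 2)
  search <- 0:k_max
  k <- search[which.max(cc[search + 1])]
  if (k == 0) {
    return(structure(
      list(transit_time = 0, peak_correlation = cc[1],
           lag_search_bounds = c(0, k_max / fs), degenerate = TRUE),
      class = "transit_time_result"))
  }
  cl <- cc[k]; cm <- cc[k + 1]; cr <- cc[((k + 1) %% n) + 1]
  denom <- cl - 2 * cm + cr
  delta <- if (denom != 0) 0.5 * (cl - cr) / denom else 0
  delta <- max(-0.5, min(0.5, delta))
  peak <- cm - 0.25 * (cl - cr) * delta
  if (peak < corr_floor)
    stop(sprintf(
      "unreliable transit-time estimate: peak correlation %.2f below %.2f",
      peak, corr_floor))
  structure(
    list(transit_time = (k + delta) / fs, peak_correlation = peak,
         lag_search_bounds = c(0, k_max / fs), degenerate = FALSE),
    class = "transit_time_result")
}

#' @export
print.transit_time_result <- function(x, ...) {
  cat(sprintf("<transit_time_result> TT = %.4f s (peak r = %.3f%s)\n",
              x$transit_time, x$peak_correlation,
              if (x$degenerate) ", degenerate" else ""))
  invisible(x)
}

#' Cycle-wise pressure summary
#'
#' DBP is the mean over cycles of the per-cycle minima and SBP the mean of
#' the per-cycle maxima; pulse pressure is `SBP - DBP` and mean arterial
#' pressure is `DBP + PP/3`.
#'
#' @param record A pressure-channel [waveform_record()].
#' @param min_cycles Minimum complete cycles required.
#' @return A `pressure_summary` object with fields `DBP`, `SBP`, `PP`,
#'   `MAP` in mmHg.
#' @export
pressure_summary <- function(record, min_cycles = 1) {
  stopifnot(inherits(record, "waveform_record"))
  if (record$channel != "pressure")
    stop("pressure_summary requires a pressure-channel record")
  ens <- segment_cycles(record, min_cycles)
  dbp <- mean(apply(ens$cycles, 1, min))
  sbp <- mean(apply(ens$cycles, 1, max))
  pressure_from_sbp_dbp(sbp, dbp)
}

#' Derived pressures from systolic and diastolic values
#'
#' Applies the study definitions `PP = SBP - DBP` and `MAP = DBP + PP/3`.
#'
#' @param sbp,dbp Systolic and diastolic pressure in mmHg (`sbp >= dbp`).
#' @return A `pressure_summary` object.
#' @examples
#' pressure_from_sbp_dbp(122, 73) # PP 49, MAP 89.3
#' @export
pressure_from_sbp_dbp <- function(sbp, dbp) {
  if (sbp < dbp) stop("SBP must be at least DBP")
  pp <- sbp - dbp
  structure(list(DBP = dbp, SBP = sbp, PP = pp, MAP = dbp + pp / 3),
            class = "pressure_summary")
}

#' @export
print.pressure_summary <- function(x, ...) {
  cat(sprintf(
    "<pressure_summary> DBP %.1f / SBP %.1f / PP %.1f / MAP %.1f mmHg\n",
    x$DBP, x$SBP, x$PP, x$MAP))
  invisible(x)
}
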