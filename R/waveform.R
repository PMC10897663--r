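#' Waveform record
#'
#' A uniformly sampled flow or pressure time series acquired at one
#' measurement site of the mock circulatory loop. Flow is stored in L/min,
#' pressure in mmHg.
#'
#' @param values Numeric vector of samples (flow in L/min or pressure in
#'   mmHg); all values must be finite.
#' @param sampling_rate Sampling rate in Hz.
#' @param site Measurement site: `"proximal"`, `"distal"` (flow meter
#'   positions) or `"zone3"` (pressure sensor).
#' @param channel `"flow"` or `"pressure"`.
#' @param heart_rate Pump rate in beats/min; cycle segmentation is
#'   synchronized to it.
#' @return An object of class `waveform_record`.
#' @examples
#' t <- seq(0, 20, by = 1e-3)
#' w <- waveform_record(100 + 20 * sin(2 * pi * t / 0.8), 1000,
#'                      site = "zone3", channel = "pressure", heart_rate = 75)
#' w
#' @export
waveform_record <- function(values, sampling_rate, site, channel, heart_rate) {
  site <- match.arg(site, c("proximal", "distal", "zone3"))
  channel <- match.arg(channel, c("flow", "pressure"))
  stopifnot(is.numeric(values), length(values) >= 2)
  if (!all(is.finite(values))) stop("waveform values must all be finite")
  if (!is.numeric(sampling_rate) || sampling_rate <= 0)
    stop("sampling_rate must be positive")
  if (!is.numeric(heart_rate) || heart_rate <= 0)
    stop("heart_rate must be positive")
  structure(
    list(values = as.numeric(values), sampling_rate = sampling_rate,
         site = site, channel = channel, heart_rate = heart_rate),
    class = "waveform_record"
  )
}

#' @export
print.waveform_record <- function(x, ...) {
  dur <- length(x$values) / x$sampling_rate
  cat(sprintf(
    "<waveform_record> %s %s: %d samples @ %g Hz (%.2f s, %g bpm)\n",
    x$site, x$channel, length(x$values), x$sampling_rate, dur, x$heart_rate))
  cat(sprintf("  range: [%.3f, %.3f] %s\n", min(x$values), max(x$values),
              if (x$channel == "flow") "L/min" else "mmHg"))
  invisible(x)
}

duration_s <- function(record) length(record$values) / record$sampling_rate
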