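# File formats: waveform CSV (`time_s,value`) with a JSON sidecar carrying
# the acquisition metadata; point-set CSV with `#`-prefixed header comments
# for the scale segment and pressure; loop configuration as JSON or YAML.

#' Write a waveform record to CSV plus JSON sidecar
#'
#' @param record A [waveform_record()].
#' @param path CSV path (`time_s,value` columns).
#' @param sidecar_path JSON sidecar path; defaults to `<path>.json`.
#' @param seed Optional acquisition seed to log in the sidecar.
#' @return Invisibly, `c(csv = path, json = sidecar_path)`.
#' @export
write_waveform_csv <- function(record, path,
                               sidecar_path = paste0(path, ".json"),
                               seed = NA) {
  stopifnot(inherits(record, "waveform_record"))
  n <- length(record$values)
  utils::write.csv(
    data.frame(time_s = (seq_len(n) - 1) / record$sampling_rate,
               value = record$values),
    path, row.names = FALSE)
  jsonlite::write_json(
    list(site = record$site, channel = record$channel,
         units = if (record$channel == "flow") "L/min" else "mmHg",
         sampling_rate_hz = record$sampling_rate,
         heart_rate_bpm = record$heart_rate, seed = seed),
    sidecar_path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(c(csv = path, json = sidecar_path))
}

#' Read a waveform record from CSV plus JSON sidecar
#'
#' @param path CSV path written by [write_waveform_csv()].
#' @param sidecar_path JSON sidecar path.
#' @return A [waveform_record()].
#' @export
read_waveform_csv <- function(path, sidecar_path = paste0(path, ".json")) {
  meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  values <- utils::read.csv(path)$value
  waveform_record(values, meta$sampling_rate_hz, meta$site, meta$channel,
                  meta$heart_rate_bpm)
}

#' Write a planar point set to CSV
#'
#' Ordered `x_px,y_px` rows; header comment lines carry the scale-segment
#' endpoints and the acquisition pressure.
#'
#' @param point_set A [planar_point_set()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_point_set_csv <- function(point_set, path) {
  stopifnot(inherits(point_set, "planar_point_set"))
  ss <- point_set$scale_segment
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# scale_segment_px: %.6f %.6f %.6f %.6f",
            ss[1, 1], ss[1, 2], ss[2, 1], ss[2, 2]),
    sprintf("# pressure_mmhg: %g", point_set$pressure),
    "x_px,y_px"), con)
  utils::write.table(point_set$points, con, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a planar point set from CSV
#'
#' @param path CSV path written by [write_point_set_csv()].
#' @return A [planar_point_set()].
#' @export
read_point_set_csv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  ss_line <- sub("^# scale_segment_px:\\s*", "",
                 grep("scale_segment_px", hdr, value = TRUE)[1])
  ss <- matrix(as.numeric(strsplit(ss_line, "\\s+")[[1]]), nrow = 2,
               byrow = TRUE)
  pressure <- as.numeric(sub("^# pressure_mmhg:\\s*", "",
                             grep("pressure_mmhg", hdr, value = TRUE)[1]))
  pts <- utils::read.csv(path, comment.char = "#")
  planar_point_set(as.matrix(pts), ss, pressure)
}

#' Write a pressure-length table to CSV
#'
#' @param fit A `length_fit` from [fit_length_pressure()].
#' @param path Output CSV path (`pressure_mmhg,length_cm`).
#' @return Invisibly, `path`.
#' @export
write_lengths_csv <- function(fit, path) {
  stopifnot(inherits(fit, "length_fit"))
  utils::write.csv(
    data.frame(pressure_mmhg = fit$pressures, length_cm = fit$lengths),
    path, row.names = FALSE)
  invisible(path)
}

config_fields <- function() names(formals(mockloop_config))

#' Write a mock-loop configuration to JSON or YAML
#'
#' Field names mirror [mockloop_config()] exactly; the format follows the
#' file extension (`.yaml`/`.yml` needs the yaml package, anything else is
#' JSON).
#'
#' @param config A [mockloop_config()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_loop_config <- function(config, path) {
  stopifnot(inherits(config, "mockloop_config"))
  x <- unclass(config)
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the yaml package is required for YAML configs")
    yaml::write_yaml(x, path)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  }
  invisible(path)
}

#' Read a mock-loop configuration from JSON or YAML
#'
#' @param path Config path written by [write_loop_config()] (or authored by
#'   hand with the same field names).
#' @return A validated [mockloop_config()].
#' @export
read_loop_config <- function(path) {
  x <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the yaml package is required for YAML configs")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  known <- setdiff(config_fields(), "pressure_windows")
  args <- x[intersect(names(x), known)]
  args <- args[!vapply(args, is.null, logical(1))] # nulls fall to defaults
  if (!is.null(x$pressure_windows))
    args$pressure_windows <- lapply(x$pressure_windows, as.numeric)
  do.call(mockloop_config, args)
}
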