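# Acceleration streams: a tibble with columns t, ax, ay, az (plus optional
# label / segment / subject metadata), sampling frequency and units carried as
# attributes.  All pipeline functions take the stream as their first argument
# and return a stream or a tibble, so calls chain with the pipe.

AXES <- c("ax", "ay", "az")

#' Construct a tri-axial acceleration stream
#'
#' An `accel_stream` is a tibble with columns `t` (seconds), `ax`, `ay`, `az`
#' (acceleration), an optional `label` column of posture classes, and two
#' attributes: the sampling frequency `fs` (Hz) and the measurement `units`
#' (`"g"` for gravitational units, `"raw"` for uncalibrated sensor counts).
#' A chest-worn ±2 g accelerometer at rest reads a gravity vector of
#' magnitude 1 g; the direction of that vector relative to a stored standing
#' reference is what distinguishes the four postures.
#'
#' @param data A data frame with numeric columns `t`, `ax`, `ay`, `az`.
#' @param fs Sampling frequency in Hz (> 0).
#' @param units `"g"` or `"raw"`.
#' @param validate Check timestamps are non-negative and strictly increasing.
#' @return An `accel_stream` tibble.
#' @export
#' @examples
#' accel_stream(data.frame(t = c(0, .02, .04), ax = 0, ay = 0, az = 1), fs = 50)
accel_stream <- function(data, fs, units = c("g", "raw"), validate = TRUE) {
  units <- match.arg(units)
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) {
    stop_config("`fs` must be a single positive number (Hz).")
  }
  missing_cols <- setdiff(c("t", AXES), names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("Stream is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "posturekit_format_error")
  }
  out <- tibble::as_tibble(data)
  for (col in c("t", AXES)) {
    if (!is.numeric(out[[col]])) {
      abort(paste0("Column `", col, "` must be numeric."),
            class = "posturekit_format_error")
    }
  }
  if ("label" %in% names(out)) out$label <- as_posture(out$label)
  if (validate && nrow(out) > 1) {
    dt <- diff(out$t)
    if (any(dt <= 0)) {
      first_bad <- which(dt <= 0)[1] + 1L
      stop_validation(paste0(
        "Timestamps must be strictly increasing; first offending row: ",
        first_bad, " (t = ", format(out$t[first_bad]), ")."))
    }
  }
  if (validate && nrow(out) > 0 && out$t[1] < 0) {
    stop_validation("Timestamps must be non-negative.")
  }
  attr(out, "fs") <- fs
  attr(out, "units") <- units
  class(out) <- c("accel_stream", class(out))
  out
}

#' @rdname accel_stream
#' @param x An `accel_stream`.
#' @export
stream_fs <- function(x) {
  fs <- attr(x, "fs")
  if (is.null(fs)) stop_config("Object carries no `fs` attribute; use accel_stream().")
  fs
}

#' @rdname accel_stream
#' @export
stream_units <- function(x) attr(x, "units") %||% "g"

# rebuild stream metadata after dplyr verbs strip attributes
restamp <- function(data, template, units = stream_units(template)) {
  accel_stream(data, fs = stream_fs(template), units = units, validate = FALSE)
}

#' Read an acceleration stream from CSV
#'
#' Reads the package's CSV dialect: a mandatory header
#' `timestamp_s,ax,ay,az`, optionally followed by a `label` column with
#' values from `posture_levels()`.  Decimal separator is `.`, encoding UTF-8.
#'
#' @param path Path to a CSV file.
#' @param fs Sampling frequency of the recording in Hz.
#' @param units Units of the stored values, `"g"` (default) or `"raw"`.
#' @return An [accel_stream()].
#' @export
read_accel_csv <- function(path, fs, units = c("g", "raw")) {
  units <- match.arg(units)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("timestamp_s", AXES)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("CSV ", path, " is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "posturekit_format_error")
  }
  df <- dplyr::rename(df, t = "timestamp_s")
  keep <- c("t", AXES, intersect(c("label", "segment", "subject"), names(df)))
  accel_stream(df[keep], fs = fs, units = units)
}

#' Write an acceleration stream to CSV
#'
#' Inverse of [read_accel_csv()]: values round-trip to within 1e-9 g.
#'
#' @param stream An [accel_stream()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_accel_csv <- function(stream, path) {
  df <- tibble::as_tibble(stream)
  df <- dplyr::rename(df, timestamp_s = "t")
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

#' Sensor calibration parameters for raw-count conversion
#'
#' The affine per-axis model of an analogue accelerometer channel:
#' `value_g = (raw - offset) / sensitivity`.  Defaults follow the Shimmer3
#' accelerometer datasheet scale of 660 mV/g with zero offset.
#'
#' @param offset Per-axis zero-g offset in raw units (length 1 or 3).
#' @param sensitivity Per-axis raw units per g (length 1 or 3, strictly
#'   positive; default 660).
#' @return A `sensor_calibration` list.
#' @export
sensor_calibration <- function(offset = 0, sensitivity = 660) {
  offset <- rep_len(as.numeric(offset), 3)
  sensitivity <- rep_len(as.numeric(sensitivity), 3)
  if (any(!is.finite(sensitivity)) || any(sensitivity <= 0)) {
    stop_config("`sensitivity` must be strictly positive on every axis.")
  }
  structure(list(offset = offset, sensitivity = sensitivity),
            class = "sensor_calibration")
}

#' Convert a raw-count stream to gravitational units
#'
#' Applies the affine sensor model per axis and clips the result to the
#' ±2 g sensor range, mirroring a saturating accelerometer.  The number of
#' clipped samples is reported with a message.
#'
#' @param stream An [accel_stream()] with `units = "raw"`.
#' @param params A [sensor_calibration()].
#' @return The stream in g units.
#' @export
raw_to_g <- function(stream, params = sensor_calibration()) {
  if (stream_units(stream) != "raw") {
    stop_validation("`raw_to_g()` expects a stream with units = \"raw\".")
  }
  stopifnot(inherits(params, "sensor_calibration"))
  out <- tibble::as_tibble(stream)
  clipped <- 0L
  for (i in seq_along(AXES)) {
    g <- (out[[AXES[i]]] - params$offset[i]) / params$sensitivity[i]
    clipped <- clipped + sum(abs(g) > 2)
    out[[AXES[i]]] <- pmin(pmax(g, -2), 2)
  }
  if (clipped > 0) {
    inform(paste0("raw_to_g: clipped ", clipped,
                  " sample value(s) to the +/-2 g sensor range."))
  }
  restamp(out, stream, units = "g")
}

#' @export
print.accel_stream <- function(x, ...) {
  cat(sprintf("<accel_stream: %d samples at %g Hz, units = %s>\n",
              nrow(x), stream_fs(x), stream_units(x)))
  NextMethod()
}
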