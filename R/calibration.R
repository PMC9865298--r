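# Standing-pose calibration: when the device is first strapped on, the wearer
# stands still for a couple of seconds.  If the sensor is mounted correctly
# the gravity axis reads ~1 g and the two orthogonal axes read ~0 g; the mean
# standing acceleration direction is stored as the per-subject reference, so
# later chest-tilt angles are measured relative to it and mounting offsets
# cancel.

#' Calibrate against a static standing recording
#'
#' Checks that a filtered standing-pose stream satisfies the mounting
#' conditions and stores the reference direction.  The checks, in order:
#' (a) the absolute mean on both non-gravity axes is at most `tolerance_g`
#' (orthogonal to gravity); (b) the absolute mean on the gravity axis is
#' within `tolerance_g` of 1 g; (c) every per-axis standard deviation is at
#' most `static_std_max_g` (the wearer was actually static).
#'
#' @param stream A filtered [accel_stream()] in g units of at least 2 s.
#' @param gravity_axis Which device axis carries gravity when standing
#'   (`"z"` by default; depends on mounting convention).
#' @param tolerance_g Mean tolerance in g on each check (default 0.15).
#' @param static_std_max_g Maximum per-axis standard deviation in g
#'   (default 0.05).
#' @return A `posture_calibration` object: stored per-axis means and
#'   standard deviations, the unit reference vector, and the thresholds.
#' @export
calibrate_standing <- function(stream, gravity_axis = c("z", "x", "y"),
                               tolerance_g = 0.15, static_std_max_g = 0.05) {
  gravity_axis <- match.arg(gravity_axis)
  if (tolerance_g <= 0 || static_std_max_g <= 0) {
    stop_config("Calibration tolerances must be positive.")
  }
  fs <- stream_fs(stream)
  if (nrow(stream) < 2 * fs) {
    abort(sprintf(
      "Calibration stream too short: %d samples (< 2 s at %g Hz).",
      nrow(stream), fs), class = "posturekit_insufficient_data_error")
  }
  means <- vapply(AXES, function(a) mean(stream[[a]]), numeric(1))
  sds <- vapply(AXES, function(a) sd(stream[[a]]), numeric(1))
  axis_letter <- substr(AXES, 2, 2)
  g_idx <- match(gravity_axis, axis_letter)

  for (i in setdiff(seq_along(AXES), g_idx)) {
    if (abs(means[i]) > tolerance_g) {
      stop_calibration(sprintf(
        "Non-gravity axis %s mean %.3f g exceeds tolerance %.3f g; device is not upright.",
        axis_letter[i], means[i], tolerance_g))
    }
  }
  if (abs(abs(means[g_idx]) - 1) > tolerance_g) {
    stop_calibration(sprintf(
      "Gravity axis %s mean %.3f g is not within %.3f g of 1 g.",
      gravity_axis, means[g_idx], tolerance_g))
  }
  for (i in seq_along(AXES)) {
    if (sds[i] > static_std_max_g) {
      stop_calibration(sprintf(
        "Static condition violated: axis %s standard deviation %.3f g exceeds %.3f g.",
        axis_letter[i], sds[i], static_std_max_g))
    }
  }
  reference <- means / sqrt(sum(means^2))
  structure(list(
    reference = unname(reference),
    stored_means = unname(means),
    stored_sds = unname(sds),
    gravity_axis = gravity_axis,
    tolerance_g = tolerance_g,
    static_std_max_g = static_std_max_g,
    fs = fs,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  ), class = "posture_calibration")
}

#' @export
print.posture_calibration <- function(x, ...) {
  cat("<posture_calibration>\n")
  cat(sprintf("  reference: (%.4f, %.4f, %.4f)\n",
              x$reference[1], x$reference[2], x$reference[3]))
  cat(sprintf("  stored means (g): (%.4f, %.4f, %.4f); sds: (%.4f, %.4f, %.4f)\n",
              x$stored_means[1], x$stored_means[2], x$stored_means[3],
              x$stored_sds[1], x$stored_sds[2], x$stored_sds[3]))
  cat(sprintf("  gravity axis: %s, tolerance %g g, static sd max %g g\n",
              x$gravity_axis, x$tolerance_g, x$static_std_max_g))
  invisible(x)
}

#' Serialize / restore a calibration profile
#'
#' Profiles are stored as small YAML documents so a run directory is fully
#' self-describing.
#'
#' @param calibration A `posture_calibration`.
#' @param path File path.
#' @return `write_calibration()` returns `path` invisibly;
#'   `read_calibration()` returns the profile.
#' @export
write_calibration <- function(calibration, path) {
  stopifnot(inherits(calibration, "posture_calibration"))
  yaml::write_yaml(unclass(calibration), path, precision = 15)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  obj <- yaml::read_yaml(path)
  needed <- c("reference", "stored_means", "gravity_axis", "tolerance_g")
  if (!all(needed %in% names(obj))) {
    abort(paste0("Not a calibration profile: ", path),
          class = "posturekit_format_error")
  }
  for (f in c("reference", "stored_means", "stored_sds")) {
    obj[[f]] <- as.numeric(obj[[f]])
  }
  structure(obj, class = "posture_calibration")
}

#' Chest-tilt angle relative to the calibration reference
#'
#' The tilt angle alpha is the angle in degrees between an acceleration
#' direction and the stored standing reference:
#' `alpha = acos(v . ref / |v|)`, clamped into `[0, 180]`.  Because the
#' reference is per-subject, mounting offsets cancel.
#'
#' @param v A length-3 numeric vector, or an n x 3 matrix of row vectors, in g.
#' @param calibration A `posture_calibration`.
#' @return Tilt angle(s) in degrees.
#' @export
#' @examples
#' cal <- structure(list(reference = c(0, 0, 1)), class = "posture_calibration")
#' tilt_angle(c(0, 1, 0), cal)  # 90
tilt_angle <- function(v, calibration) {
  stopifnot(inherits(calibration, "posture_calibration"))
  if (is.null(dim(v))) v <- matrix(v, nrow = 1)
  stopifnot(ncol(v) == 3)
  mag <- sqrt(rowSums(v^2))
  if (any(mag < 0.1)) {
    abort("Acceleration magnitude below 0.1 g: free fall or sensor disconnection.",
          class = "posturekit_signal_loss_error")
  }
  cosa <- (v %*% calibration$reference)[, 1] / mag
  acos(pmin(pmax(cosa, -1), 1)) * 180 / pi
}

#' Add a per-sample chest-tilt column to a stream
#'
#' @param stream An [accel_stream()] in g units (ideally low-pass filtered).
#' @param calibration A `posture_calibration`.
#' @return The stream with an extra `tilt_deg` column.
#' @export
stream_tilt <- function(stream, calibration) {
  v <- as.matrix(tibble::as_tibble(stream)[AXES])
  out <- tibble::as_tibble(stream)
  out$tilt_deg <- tilt_angle(v, calibration)
  restamp(out, stream)
}
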