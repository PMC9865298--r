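# Low-pass noise filtering.  The pipeline's main filter is an order-8
# Butterworth with 10 Hz cutoff; electrical and environmental noise sits above
# the postural band while voluntary trunk movement stays well below 10 Hz.

#' Low-pass filter an acceleration stream
#'
#' Applies a Butterworth low-pass filter to each axis.  Two modes:
#' `"zero_phase"` (default, batch processing) runs the filter
#' forward-backward, which cancels group delay but squares the magnitude
#' response (the effective attenuation order doubles); `"causal"` applies a
#' single forward pass, matching what a real-time implementation sees.
#'
#' @param stream An [accel_stream()] in g units.
#' @param cutoff_hz Cut-off frequency in Hz (default 10); must be below the
#'   Nyquist frequency `fs / 2`.
#' @param order Filter order (default 8).
#' @param mode `"zero_phase"` or `"causal"`.
#' @return The filtered stream; timestamps and length unchanged, DC gain 1.
#' @export
#' @examples
#' s <- accel_stream(data.frame(t = (0:99) / 50, ax = 0, ay = 0, az = 1), fs = 50)
#' f <- lowpass_filter(s)
#' all.equal(f$az, s$az)  # constant input passes unchanged
lowpass_filter <- function(stream, cutoff_hz = 10, order = 8,
                           mode = c("zero_phase", "causal")) {
  mode <- match.arg(mode)
  fs <- stream_fs(stream)
  if (!is.numeric(order) || order < 1) stop_config("`order` must be >= 1.")
  if (cutoff_hz <= 0 || cutoff_hz >= fs / 2) {
    stop_config(sprintf(
      "`cutoff_hz` (%g) must lie in (0, fs/2) = (0, %g).", cutoff_hz, fs / 2))
  }
  bf <- signal::butter(order, cutoff_hz / (fs / 2), type = "low")
  # odd-reflection padding long enough for the filter transient to die out,
  # so the forward-backward pass is transient-free at the stream edges
  padlen <- max(12 * (order + 1), ceiling(3 * fs / cutoff_hz))
  out <- tibble::as_tibble(stream)
  for (axis in AXES) {
    x <- out[[axis]]
    out[[axis]] <- if (mode == "zero_phase") {
      filtfilt_padded(bf, x, padlen)
    } else {
      as.numeric(signal::filter(bf, x))
    }
  }
  restamp(out, stream)
}

filtfilt_padded <- function(bf, x, padlen) {
  n <- length(x)
  padlen <- min(padlen, n - 1)
  ext <- if (padlen > 0) {
    c(2 * x[1] - x[seq(padlen + 1, 2)], x,
      2 * x[n] - x[seq(n - 1, n - padlen)])
  } else x
  fwd <- as.numeric(signal::filter(bf, ext))
  y <- rev(as.numeric(signal::filter(bf, rev(fwd))))
  y[(padlen + 1):(padlen + n)]
}

#' Extract the static (gravity) acceleration component
#'
#' A very-low-cutoff low-pass that isolates the slowly varying gravity
#' projection from movement-induced dynamic acceleration.  Feeds the
#' static-acceleration-change (SAC) feature.  The default order-2 design
#' tracks postural drift without ringing at the very low normalised cutoff.
#'
#' @param stream A (typically already noise-filtered) [accel_stream()].
#' @param cutoff_hz Static cutoff in Hz, default 0.5; must be below the main
#'   filter cutoff.
#' @param order Filter order, default 2.
#' @param mode As in [lowpass_filter()].
#' @return A stream of the same length holding the static component.
#' @export
compute_static_component <- function(stream, cutoff_hz = 0.5, order = 2,
                                     mode = c("zero_phase", "causal")) {
  lowpass_filter(stream, cutoff_hz = cutoff_hz, order = order,
                 mode = match.arg(mode))
}
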