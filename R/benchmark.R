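# Real-time benchmarking.  Each incoming window must be classified before
# the next sensor sample arrives, so the criterion is: mean per-window
# latency (feature extraction + prediction) below the sampling period
# (20 ms at 50 Hz).  Absolute times are hardware-bound; only
# machine-relative statements (orderings, the real-time boolean) are
# meaningful across platforms.

#' Measure per-window inference latency
#'
#' Replays a stream window by window and times the full per-window path —
#' slicing, time-domain feature extraction and model prediction — pooling
#' the per-window latencies over `repetitions` replays.
#'
#' @param model A fitted `posture_model`.
#' @param stream A filtered [accel_stream()].
#' @param spec A [window_spec()].
#' @param repetitions Number of replays to average over (default 10).
#' @param static_cutoff_hz,static_order Static-component design, as in
#'   [posture_features()].
#' @return A `posture_benchmark`: mean / median / 95th-percentile latency in
#'   seconds, the sampling period, and `real_time_ok` (mean latency below
#'   the sampling period).
#' @export
benchmark_inference <- function(model, stream, spec = window_spec(),
                                repetitions = 10,
                                static_cutoff_hz = 0.5, static_order = 2) {
  stopifnot(inherits(model, "posture_model"))
  if (repetitions < 1) stop_config("`repetitions` must be >= 1.")
  fs <- stream_fs(stream)
  wins <- make_windows(stream, spec)
  if (nrow(wins) == 0) stop_validation("Stream holds no complete window.")
  static <- compute_static_component(stream, cutoff_hz = static_cutoff_hz,
                                     order = static_order)
  dyn_m <- as.matrix(tibble::as_tibble(stream)[AXES])
  sta_m <- as.matrix(tibble::as_tibble(static)[AXES])
  layout_cols <- model$schema

  lat <- numeric(0)
  for (rep_i in seq_len(repetitions)) {
    times <- vapply(seq_len(nrow(wins)), function(w) {
      rows <- wins$start[w]:wins$end[w]
      t0 <- Sys.time()
      fv <- window_features(dyn_m[rows, , drop = FALSE],
                            sta_m[rows, , drop = FALSE])
      row <- tibble::as_tibble(as.list(fv[layout_cols]))
      predict(model, row)
      as.numeric(difftime(Sys.time(), t0, units = "secs"))
    }, numeric(1))
    lat <- c(lat, times)
  }
  lat <- pmax(lat, .Machine$double.eps)
  period <- 1 / fs
  structure(list(
    kind = model$config$kind,
    mean_latency_s = mean(lat), median_latency_s = stats::median(lat),
    p95_latency_s = unname(quantile(lat, 0.95)),
    sampling_period_s = period,
    real_time_ok = mean(lat) < period,
    repetitions = repetitions, n_windows = nrow(wins),
    latencies_s = lat), class = "posture_benchmark")
}

#' @export
print.posture_benchmark <- function(x, ...) {
  cat(sprintf(
    "<posture_benchmark %s: mean %.2f ms, median %.2f ms, p95 %.2f ms over %d windows x %d reps>\n",
    toupper(x$kind), 1000 * x$mean_latency_s, 1000 * x$median_latency_s,
    1000 * x$p95_latency_s, x$n_windows, x$repetitions))
  cat(sprintf("  sampling period %.0f ms; real-time: %s\n",
              1000 * x$sampling_period_s, if (x$real_time_ok) "OK" else "NO"))
  invisible(x)
}

#' Serialize / restore a benchmark report
#'
#' JSON round-trip; numeric fields survive losslessly.
#'
#' @param report A `posture_benchmark`.
#' @param path File path.
#' @return The path (write) or the restored report (read).
#' @export
write_benchmark <- function(report, path) {
  stopifnot(inherits(report, "posture_benchmark"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_benchmark
#' @export
read_benchmark <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(obj, class = "posture_benchmark")
}

#' @export
tidy.posture_benchmark <- function(x, ...) {
  tibble::tibble(kind = x$kind, mean_latency_s = x$mean_latency_s,
                 median_latency_s = x$median_latency_s,
                 p95_latency_s = x$p95_latency_s,
                 sampling_period_s = x$sampling_period_s,
                 real_time_ok = x$real_time_ok)
}

#' Sample process CPU and memory utilisation
#'
#' Probes the running R process over `duration_s` seconds using the system
#' `ps` utility and reports mean CPU and RAM percentages.  On platforms
#' without `ps` the fields are `NA` and `available` is `FALSE` — resource
#' sampling degrades gracefully instead of failing.
#'
#' @param duration_s Sampling duration in seconds (default 0.5).
#' @param interval_s Probe spacing in seconds (default 0.1).
#' @return A list: `cpu_percent`, `ram_percent` (in `[0, 100]` or `NA`),
#'   `available`.
#' @export
sample_resources <- function(duration_s = 0.5, interval_s = 0.1) {
  probe <- function() {
    out <- tryCatch(
      suppressWarnings(system2("ps", c("-o", "%cpu=,%mem=", "-p",
                                       Sys.getpid()),
                               stdout = TRUE, stderr = FALSE)),
      error = function(e) character(0))
    vals <- suppressWarnings(as.numeric(strsplit(trimws(out[1]),
                                                 "\\s+")[[1]]))
    if (length(vals) == 2 && !anyNA(vals)) vals else NULL
  }
  t_end <- Sys.time() + duration_s
  samples <- list()
  repeat {
    p <- probe()
    if (!is.null(p)) samples[[length(samples) + 1L]] <- p
    if (Sys.time() >= t_end) break
    Sys.sleep(interval_s)
  }
  if (length(samples) == 0) {
    return(list(cpu_percent = NA_real_, ram_percent = NA_real_,
                available = FALSE))
  }
  m <- do.call(rbind, samples)
  list(cpu_percent = min(max(mean(m[, 1]), 0), 100),
       ram_percent = min(max(mean(m[, 2]), 0), 100),
       available = TRUE)
}
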