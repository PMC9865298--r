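# Synthetic chest-IMU generator.  A chest-worn ±2 g accelerometer at rest
# measures the gravity direction in the device frame; the four static
# postures differ by the chest tilt angle theta about the device x-axis.
# Per sample the noiseless gravity vector is
#     R(mounting offset) %*% c(0, sin(theta), cos(theta))   [magnitude 1 g]
# to which a breathing sinusoid along the chest normal and white sensor
# noise are added, and the result is clipped to the ±2 g range.

#' Default posture models
#'
#' Per-posture generative parameters: the mean chest-tilt in degrees, the
#' within-bout angular jitter (fast postural tremor, per-sample sd), the
#' white dynamic-noise sd in g, and the breathing sinusoid amplitude and
#' rate.  Sitting sits closer to standing (20 deg) than bending (60 deg) and
#' lying (90 deg), reflecting that a single chest device most easily
#' confuses standing/sitting and bending/lying.
#'
#' @return A tibble with one row per posture.
#' @export
default_postures <- function() {
  tibble::tibble(
    posture = posture_levels(),
    tilt_mean_deg = c(0, 20, 60, 90),
    tilt_std_deg = c(4, 5, 8, 6),
    dynamic_noise_g = 0.02,
    breathing_amp_g = 0.005,
    breathing_hz = 0.25)
}

#' Posture schedule
#'
#' An ordered sequence of (posture, duration) bouts with smooth transitions.
#' The default cycles all four postures three times at 30 s per bout.
#'
#' @param postures Character vector of posture names for one cycle.
#' @param duration_s Bout duration in seconds (recycled).
#' @param cycles How many times to repeat the cycle.
#' @param transition_s Smooth tilt-interpolation time between bouts
#'   (default 1 s).
#' @return A tibble with columns `segment`, `posture`, `duration_s`,
#'   `transition_s`.
#' @export
posture_schedule <- function(postures = posture_levels(), duration_s = 30,
                             cycles = 3, transition_s = 1) {
  if (any(duration_s <= 0)) stop_config("Bout durations must be positive.")
  seq_post <- rep(rep(postures, length.out = length(postures)), cycles)
  tibble::tibble(segment = seq_along(seq_post),
                 posture = as.character(seq_post),
                 duration_s = rep(rep_len(duration_s, length(postures)), cycles),
                 transition_s = transition_s)
}

rot_x <- function(deg) {
  a <- deg * pi / 180
  matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
}
rot_y <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
}

#' Simulate a labelled chest-acceleration stream
#'
#' Generates one recording following `schedule`.  The chest tilt follows the
#' scheduled posture means, cosine-interpolated over `transition_s` at each
#' bout change (transition samples carry the incoming posture's label), with
#' per-sample Gaussian angular jitter of the current posture's
#' `tilt_std_deg`.  Deterministic given `seed`.
#'
#' @param schedule A [posture_schedule()].
#' @param postures A posture-model table as from [default_postures()].
#' @param fs Sampling frequency in Hz (default 50).
#' @param seed Integer seed.
#' @param mounting_offset_deg Length-2 rotation offsets (about the device x
#'   and y axes) modelling imperfect sensor placement.
#' @param noise_scale Multiplier on the dynamic-noise sd.
#' @return An [accel_stream()] in g units with `label` and `segment` columns.
#' @export
#' @examples
#' s <- simulate_stream(posture_schedule(duration_s = 2, cycles = 1), seed = 1)
simulate_stream <- function(schedule, postures = default_postures(), fs = 50,
                            seed = 0L, mounting_offset_deg = c(0, 0),
                            noise_scale = 1) {
  if (nrow(schedule) == 0 || any(schedule$duration_s <= 0)) {
    stop_config("Schedule must contain bouts of positive duration.")
  }
  if (any(abs(mounting_offset_deg) >= 15)) {
    stop_config("Mounting offsets must stay below 15 degrees.")
  }
  missing_post <- setdiff(schedule$posture, postures$posture)
  if (length(missing_post) > 0) {
    stop_config(paste0("Schedule uses unmodelled posture(s): ",
                       paste(missing_post, collapse = ", ")))
  }
  set.seed(as.integer(seed))
  R <- rot_x(mounting_offset_deg[1]) %*% rot_y(mounting_offset_deg[2])
  breathing_phase <- stats::runif(1, 0, 2 * pi)

  n_seg <- vapply(schedule$duration_s, function(d) as.integer(round(d * fs)),
                  integer(1))
  n <- sum(n_seg)
  seg_of <- rep(schedule$segment, n_seg)
  pos_of <- rep(schedule$posture, n_seg)
  pidx <- match(pos_of, postures$posture)
  mean_tilt <- postures$tilt_mean_deg[pidx]

  # cosine-interpolated base tilt over each bout change
  theta <- mean_tilt
  offs <- cumsum(c(0, n_seg[-length(n_seg)]))
  for (s in seq_len(nrow(schedule))[-1]) {
    n_tr <- min(as.integer(round(schedule$transition_s[s] * fs)), n_seg[s])
    if (n_tr > 0) {
      u <- (seq_len(n_tr) - 0.5) / n_tr
      prev <- postures$tilt_mean_deg[match(schedule$posture[s - 1],
                                           postures$posture)]
      cur <- postures$tilt_mean_deg[match(schedule$posture[s],
                                          postures$posture)]
      theta[offs[s] + seq_len(n_tr)] <- prev + (cur - prev) * (1 - cos(pi * u)) / 2
    }
  }
  theta <- theta + postures$tilt_std_deg[pidx] * rnorm(n)
  th <- theta * pi / 180
  gvec <- R %*% rbind(0, sin(th), cos(th))  # unit magnitude by construction

  normal <- R %*% c(0, 0, 1)
  t <- (seq_len(n) - 1) / fs
  breath <- postures$breathing_amp_g[pidx] *
    sin(2 * pi * postures$breathing_hz[pidx] * t + breathing_phase)
  noise_sd <- noise_scale * postures$dynamic_noise_g[pidx]
  acc <- t(gvec) + outer(breath, as.numeric(normal)) +
    matrix(rnorm(3 * n, sd = noise_sd), n, 3)
  acc <- pmin(pmax(acc, -2), 2)

  accel_stream(tibble::tibble(
    t = t, ax = acc[, 1], ay = acc[, 2], az = acc[, 3],
    label = pos_of, segment = seg_of), fs = fs, validate = FALSE)
}

#' Simulate a cohort of subjects
#'
#' Emulates a multi-subject study: each subject gets a random mounting
#' offset (sd `mounting_sd_deg` about the x and y device axes, truncated
#' below 15 degrees), a mild random noise-scale perturbation, and an
#' independent stream following `schedule`.  Deterministic given `seed`.
#'
#' @param n_subjects Number of subjects (default 7).
#' @param seed Integer seed.
#' @param schedule A [posture_schedule()] shared by all subjects.
#' @param postures A posture-model table.
#' @param fs Sampling frequency in Hz.
#' @param mounting_sd_deg Sd of the per-subject mounting offsets (default 3).
#' @return A single tibble of all streams stacked, with a `subject` column;
#'   carries `fs` and `units` attributes like an [accel_stream()].
#' @export
simulate_cohort <- function(n_subjects = 7, seed = 0L,
                            schedule = posture_schedule(),
                            postures = default_postures(), fs = 50,
                            mounting_sd_deg = 3) {
  set.seed(as.integer(seed))
  offsets <- matrix(rnorm(2 * n_subjects, sd = mounting_sd_deg), n_subjects, 2)
  offsets <- pmin(pmax(offsets, -14.9), 14.9)
  noise_scales <- stats::runif(n_subjects, 0.9, 1.1)
  subject_seeds <- sample.int(.Machine$integer.max - 1L, n_subjects)
  cal_seeds <- sample.int(.Machine$integer.max - 1L, n_subjects)
  streams <- lapply(seq_len(n_subjects), function(s) {
    st <- simulate_stream(schedule, postures = postures, fs = fs,
                          seed = subject_seeds[s],
                          mounting_offset_deg = offsets[s, ],
                          noise_scale = noise_scales[s])
    st$subject <- s
    tibble::as_tibble(st)
  })
  out <- dplyr::bind_rows(streams)
  attr(out, "fs") <- fs
  attr(out, "units") <- "g"
  attr(out, "subjects") <- tibble::tibble(
    subject = seq_len(n_subjects),
    offset_x_deg = offsets[, 1], offset_y_deg = offsets[, 2],
    noise_scale = noise_scales, stream_seed = subject_seeds,
    cal_seed = cal_seeds)
  attr(out, "postures") <- postures
  out
}

#' Simulate the per-subject calibration acquisitions of a cohort
#'
#' The calibration protocol is a short, guided standing hold performed right
#' after the device is strapped on: the wearer deliberately stands still, so
#' postural sway during this acquisition is smaller than during natural
#' activity.  This generates that dedicated hold for every subject of a
#' simulated cohort, with the subject's own mounting offset.
#'
#' @param cohort A cohort tibble from [simulate_cohort()] (must carry its
#'   `subjects` attribute).
#' @param duration_s Hold duration in seconds (default 4).
#' @param stillness Factor applied to the standing tilt jitter during the
#'   instructed hold (default 0.5).
#' @return A named list of standing [accel_stream()]s, one per subject.
#' @export
cohort_calibration_streams <- function(cohort, duration_s = 4,
                                       stillness = 0.5) {
  info <- attr(cohort, "subjects")
  if (is.null(info)) {
    stop_config(paste0("Cohort carries no per-subject parameters; ",
                       "calibrate on a standing bout instead."))
  }
  postures <- attr(cohort, "postures") %||% default_postures()
  postures$tilt_std_deg <- postures$tilt_std_deg * stillness
  fs <- attr(cohort, "fs") %||% 50
  sched <- posture_schedule("standing", duration_s = duration_s, cycles = 1)
  out <- lapply(seq_len(nrow(info)), function(i) {
    simulate_stream(sched, postures = postures, fs = fs,
                    seed = info$cal_seed[i],
                    mounting_offset_deg = c(info$offset_x_deg[i],
                                            info$offset_y_deg[i]),
                    noise_scale = info$noise_scale[i])
  })
  names(out) <- paste0("subject_", info$subject)
  out
}

#' Per-subject streams of a cohort table
#'
#' Splits the stacked cohort tibble back into per-subject
#' [accel_stream()]s.
#'
#' @param cohort A tibble from [simulate_cohort()] (or the same shape).
#' @param fs Sampling frequency; defaults to the cohort's `fs` attribute.
#' @return A named list of `accel_stream`s, one per subject.
#' @export
cohort_streams <- function(cohort, fs = attr(cohort, "fs")) {
  if (is.null(fs)) stop_config("Cohort carries no `fs`; pass it explicitly.")
  split_ids <- unique(cohort$subject)
  out <- lapply(split_ids, function(s) {
    accel_stream(cohort[cohort$subject == s, , drop = FALSE], fs = fs,
                 validate = FALSE)
  })
  names(out) <- paste0("subject_", split_ids)
  out
}
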