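noiseless_postures <- function() {
  p <- default_postures()
  p$tilt_std_deg <- 0
  p$dynamic_noise_g <- 0
  p$breathing_amp_g <- 0
  p
}

test_that("noiseless postures produce the exact gravity projections", {
  stand <- simulate_stream(
    posture_schedule("standing", duration_s = 2, cycles = 1),
    postures = noiseless_postures(), seed = 1)
  expect_equal(stand$ax, rep(0, 100), tolerance = 1e-12)
  expect_equal(stand$ay, rep(0, 100), tolerance = 1e-12)
  expect_equal(stand$az, rep(1, 100), tolerance = 1e-12)

  lying <- simulate_stream(
    posture_schedule("lying", duration_s = 2, cycles = 1),
    postures = noiseless_postures(), seed = 1)
  expect_equal(lying$ay, rep(1, 100), tolerance = 1e-12)
  expect_equal(lying$az, rep(0, 100), tolerance = 1e-12)
})

test_that("generated gravity vectors have unit magnitude before noise", {
  p <- default_postures()
  p$dynamic_noise_g <- 0
  p$breathing_amp_g <- 0
  s <- simulate_stream(posture_schedule(duration_s = 3, cycles = 1),
                       postures = p, seed = 4,
                       mounting_offset_deg = c(4, -2))
  mag <- sqrt(s$ax^2 + s$ay^2 + s$az^2)
  expect_equal(mag, rep(1, nrow(s)), tolerance = 1e-12)
})

test_that("generation is seed-deterministic", {
  sched <- posture_schedule(duration_s = 2, cycles = 1)
  a <- simulate_stream(sched, seed = 9)
  b <- simulate_stream(sched, seed = 9)
  c <- simulate_stream(sched, seed = 10)
  expect_identical(a$az, b$az)
  expect_false(identical(a$az, c$az))
  co1 <- simulate_cohort(2, seed = 5, schedule = sched)
  co2 <- simulate_cohort(2, seed = 5, schedule = sched)
  expect_identical(co1, co2)
})

test_that("schedule validation rejects bad input", {
  expect_error(posture_schedule(duration_s = -1),
               class = "posturekit_config_error")
  expect_error(simulate_stream(posture_schedule("standing")[0, ]),
               class = "posturekit_config_error")
  sched <- posture_schedule("standing", duration_s = 2, cycles = 1)
  expect_error(simulate_stream(sched, mounting_offset_deg = c(20, 0)),
               class = "posturekit_config_error")
  bad <- sched
  bad$posture <- "crouching"
  expect_error(simulate_stream(bad), class = "posturekit_config_error")
})

test_that("transition samples carry the incoming posture's label", {
  sched <- posture_schedule(c("standing", "lying"), duration_s = 2,
                            cycles = 1, transition_s = 1)
  s <- simulate_stream(sched, postures = noiseless_postures(), seed = 1)
  second <- s[s$segment == 2, ]
  expect_true(all(second$label == "lying"))
  # mid-transition the tilt is between the two posture means
  mid <- second[10, ]
  expect_gt(mid$ay, 0.05)
  expect_lt(mid$ay, 0.95)
  # after the 1 s transition the lying orientation is reached
  expect_equal(tail(second$ay, 20), rep(1, 20), tolerance = 1e-9)
})

test_that("the default cohort covers all subjects and balances classes", {
  co <- simulate_cohort(7, seed = 0)
  expect_equal(sort(unique(co$subject)), 1:7)
  expect_setequal(as.character(unique(co$label)), posture_levels())
  frac <- table(co$label) / nrow(co)
  expect_true(all(abs(frac - 0.25) < 0.025))  # within 10% of uniform
})

test_that("per-posture window tilt recovers the generator means within 3 degrees", {
  errs <- c()
  for (seed in 0:4) {
    co <- simulate_cohort(2, seed = seed,
                          schedule = posture_schedule(duration_s = 15,
                                                      cycles = 1))
    streams <- cohort_streams(co)
    for (st in streams) {
      st <- lowpass_filter(st)
      standing <- st[st$segment == 1, ]
      cal <- calibrate_standing(accel_stream(standing, fs = 50,
                                             validate = FALSE))
      wins <- make_windows(st)
      vm <- cbind(
        vapply(seq_len(nrow(wins)), function(w)
          mean(st$ax[wins$start[w]:wins$end[w]]), numeric(1)),
        vapply(seq_len(nrow(wins)), function(w)
          mean(st$ay[wins$start[w]:wins$end[w]]), numeric(1)),
        vapply(seq_len(nrow(wins)), function(w)
          mean(st$az[wins$start[w]:wins$end[w]]), numeric(1)))
      tilt <- tilt_angle(vm, cal)
      lab <- st$label[wins$start]
      seg <- st$segment[wins$start]
      # exclude windows near bout changes (transition interpolation)
      core <- vapply(seq_len(nrow(wins)), function(w) {
        rows <- wins$start[w]:wins$end[w]
        length(unique(st$segment[rows])) == 1 &&
          wins$start[w] > match(seg[w], st$segment) + 60
      }, logical(1))
      mean_tilt <- tapply(tilt[core], as.character(lab[core]), mean)
      truth <- setNames(default_postures()$tilt_mean_deg,
                        default_postures()$posture)
      errs <- c(errs, abs(mean_tilt - truth[names(mean_tilt)]))
    }
  }
  expect_lt(max(errs), 3)
})

test_that("postures are separable by mean tilt alone", {
  co <- simulate_cohort(3, seed = 1,
                        schedule = posture_schedule(duration_s = 10, cycles = 1))
  streams <- cohort_streams(co)
  rows <- list()
  for (st in streams) {
    st <- lowpass_filter(st)
    cal <- calibrate_standing(accel_stream(st[st$segment == 1, ], fs = 50,
                                           validate = FALSE))
    wins <- make_windows(st)
    vm <- vapply(seq_len(nrow(wins)), function(w) {
      rows_w <- wins$start[w]:wins$end[w]
      c(mean(st$ax[rows_w]), mean(st$ay[rows_w]), mean(st$az[rows_w]))
    }, numeric(3))
    rows[[length(rows) + 1]] <- tibble::tibble(
      tilt = tilt_angle(t(vm), cal),
      label = st$label[wins$start])
  }
  d <- dplyr::bind_rows(rows)
  stump <- fit_posture(d, dt_config(max_depth = 2))
  acc <- mean(predict(stump, d) == d$label)
  expect_gt(acc, 0.95)
})
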