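test_that("window sample counts follow the ceiling rule", {
  s50 <- const_stream(0, 0, 1, n = 100, fs = 50)
  w <- make_windows(s50, window_spec(350, 50))
  # 350 ms at 50 Hz = 17.5 samples -> 18; 50 ms = 2.5 -> 3
  expect_equal(w$end[1] - w$start[1] + 1, 18)
  expect_equal(w$start[2] - w$start[1], 3)
  expect_equal(nrow(w), (100 - 18) %/% 3 + 1)  # 28 windows

  s25 <- const_stream(0, 0, 1, n = 40, fs = 25)
  w25 <- make_windows(s25, window_spec(350, 50))
  expect_equal(w25$end[1] - w25$start[1] + 1, 9)   # ceil(8.75)
  expect_equal(w25$start[2] - w25$start[1], 2)     # ceil(1.25)
})

test_that("boundary and degenerate window cases behave as specified", {
  exact <- const_stream(0, 0, 1, n = 18, fs = 50)
  expect_equal(nrow(make_windows(exact)), 1)
  short <- const_stream(0, 0, 1, n = 10, fs = 50)
  expect_warning(w <- make_windows(short), "shorter")
  expect_equal(nrow(w), 0)
  expect_error(window_features(matrix(0, 1, 3)),
               class = "posturekit_window_error")
})

test_that("constant windows hit the closed-form feature values", {
  n <- 18
  c0 <- 0.7
  fv <- window_features(matrix(c0, n, 3))
  expect_equal(fv[["MAV_x"]], abs(c0))
  expect_equal(fv[["VAR_y"]], 0)
  expect_equal(fv[["STD_z"]], 0)
  expect_equal(fv[["RMS_x"]], abs(c0))
  expect_equal(fv[["DAC_y"]], 0)
  expect_equal(fv[["SKEW_z"]], 0)   # degenerate-sigma rule
  expect_equal(fv[["KURT_x"]], 0)
  expect_equal(fv[["WENT_y"]], log(n))
})

test_that("a forced small window gives hand-computed values", {
  w <- matrix(c(0.1, 0.5, 0.3), 3, 3)
  fv <- window_features(w)
  expect_equal(fv[["DAC_x"]], 0.4)
  expect_equal(fv[["MAX_y"]], 0.5)
  expect_equal(fv[["MIN_z"]], 0.1)
  expect_equal(fv[["MAV_x"]], 0.3)
})

test_that("every family matches the brute-force oracle on random windows", {
  set.seed(100)
  for (i in 1:60) {
    dyn <- matrix(runif(54, -2, 2), 18, 3)
    sta <- matrix(runif(54, -1, 1), 18, 3)
    fv <- window_features(dyn, sta)
    for (ai in 1:3) {
      oracle <- oracle_features(dyn[, ai], sta[, ai])
      got <- fv[paste0(names(oracle), "_", c("x", "y", "z")[ai])]
      expect_equal(unname(got), unname(oracle), tolerance = 1e-10)
    }
  }
})

test_that("feature identities hold exactly and features are permutation-invariant", {
  set.seed(101)
  for (i in 1:25) {
    a <- rnorm(18)
    fv <- window_features(cbind(a, a, a))
    expect_equal(fv[["SSI_x"]], 18 * fv[["RMS_x"]]^2, tolerance = 1e-9)
    expect_equal(fv[["DAC_x"]], fv[["MAX_x"]] - fv[["MIN_x"]])
    expect_lte(fv[["MIN_x"]], mean(a))
    expect_gte(fv[["MAX_x"]], mean(a))
    expect_equal(fv[["STD_x"]], sqrt(fv[["VAR_x"]]), tolerance = 1e-12)
    shuffled <- sample(a)
    fv2 <- window_features(cbind(shuffled, shuffled, shuffled))
    expect_equal(fv2, fv, tolerance = 1e-12)
  }
})

test_that("the batch path agrees with per-window extraction", {
  set.seed(55)
  n <- 120
  s <- signal_stream(rnorm(n, sd = 0.3), rnorm(n, sd = 0.3),
                     1 + rnorm(n, sd = 0.3))
  feats <- posture_features(s, layout = "full")
  static <- compute_static_component(s)
  wins <- make_windows(s)
  dyn_m <- as.matrix(tibble::as_tibble(s)[c("ax", "ay", "az")])
  sta_m <- as.matrix(tibble::as_tibble(static)[c("ax", "ay", "az")])
  for (w in c(1, 7, nrow(wins))) {
    rows <- wins$start[w]:wins$end[w]
    fv <- window_features(dyn_m[rows, ], sta_m[rows, ])
    expect_equal(unlist(feats[w, names(fv)]), fv, tolerance = 1e-12)
  }
})

test_that("feature matrix layouts have the documented shape and order", {
  s <- const_stream(0, 0, 1, n = 100)
  full <- posture_features(s, layout = "full")
  expect_equal(nrow(full), 28)
  expect_equal(sum(grepl("_[xyz]$", names(full))), 39)
  sel <- posture_features(s, layout = "selected")
  feat_cols <- grep("_[xyz]$", names(sel), value = TRUE)
  expect_equal(feat_cols, as.vector(t(outer(selected_families(),
                                            c("x", "y", "z"),
                                            paste, sep = "_"))))
  expect_false("label" %in% names(sel))  # unlabeled input stays unlabeled
})

test_that("window labels are the majority vote with ties to the earlier label", {
  n <- 40
  lab <- rep(c("standing", "sitting"), each = n / 2)
  s <- accel_stream(data.frame(t = (0:(n - 1)) / 50, ax = 0, ay = 0, az = 1,
                               label = lab), fs = 50)
  feats <- posture_features(s)
  wins <- make_windows(s)
  for (w in seq_len(nrow(wins))) {
    counts <- table(lab[wins$start[w]:wins$end[w]])
    n_stand <- sum(lab[wins$start[w]:wins$end[w]] == "standing")
    n_sit <- 18 - n_stand
    expected <- if (n_stand > n_sit) "standing"
                else if (n_sit > n_stand) "sitting"
                else "standing"  # tie: standing occurs earlier in the window
    expect_equal(as.character(feats$label[w]), expected)
  }
})

test_that("identical repeated windows yield identical feature rows", {
  base <- c(0.2, -0.1, 0.4, 0.05, -0.3, 0.25, 0.1, -0.2, 0.15,
            0.3, -0.05, 0.2, 0.0, 0.1, -0.15, 0.35, -0.25, 0.05)
  x <- rep(base, 12)
  s <- signal_stream(x, fs = 50)
  feats <- posture_features(s, spec = window_spec(360, 360), layout = "full")
  interior <- 3:(nrow(feats) - 2)
  # SAC is computed on the stream-level static component, whose filter state
  # legitimately depends on position in the stream; all other families are
  # pure functions of the window content
  for (col in grep("^(?!SAC)[A-Z]+_[xyz]$", names(feats), value = TRUE,
                   perl = TRUE)) {
    expect_lt(max(abs(feats[[col]][interior] - feats[[col]][interior][1])),
              1e-6)
  }
})

test_that("feature matrices round-trip through CSV", {
  set.seed(9)
  s <- accel_stream(data.frame(t = (0:99) / 50, ax = rnorm(100, 0, 0.1),
                               ay = rnorm(100, 0, 0.1), az = 1,
                               label = "standing"), fs = 50)
  feats <- posture_features(s)
  path <- withr::local_tempfile(fileext = ".csv")
  write_features_csv(feats, path)
  back <- read_features_csv(path)
  expect_equal(back$MAV_z, feats$MAV_z, tolerance = 1e-9)
  expect_equal(as.character(back$label), as.character(feats$label))
})
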