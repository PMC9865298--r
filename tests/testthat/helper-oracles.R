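# Independent oracles used across the suite.  These are deliberately written
# as plain loops / closed forms, independent of the package implementation.

# brute-force evaluation of all 13 feature families on one axis:
# a = window samples, s = static-component samples of the same window
oracle_features <- function(a, s = a) {
  N <- length(a)
  mu <- sum(a) / N
  varr <- sum((a - mu)^2) / N
  stdd <- sqrt(varr)
  ssi <- sum(a^2)
  p <- a^2 / ssi
  went <- 0
  for (pi in p) if (pi > 0) went <- went - pi * log(pi)
  skew <- if (stdd < 1e-12) 0 else (sum((a - mu)^3) / N) / stdd^3
  kurt <- if (stdd < 1e-12) 0 else (sum((a - mu)^4) / N) / stdd^4
  c(MAV = sum(abs(a)) / N, STD = stdd, VAR = varr, MAX = max(a),
    MIN = min(a), RMS = sqrt(ssi / N), SSI = ssi, WENT = went,
    SKEW = skew, KURT = kurt, DAC = max(a) - min(a),
    SAC = max(s) - min(s), LEE = sum(log2(a^2 + 1e-12)))
}

# closed-form Butterworth magnitude response for a single causal pass
butter_gain <- function(order, cutoff_hz, f_hz) {
  1 / sqrt(1 + (f_hz / cutoff_hz)^(2 * order))
}

# least-squares amplitude of a sinusoid of known frequency
sine_amplitude <- function(t, x, f_hz) {
  fit <- stats::lm(x ~ sin(2 * pi * f_hz * t) + cos(2 * pi * f_hz * t))
  sqrt(sum(stats::coef(fit)[2:3]^2))
}

# a constant-orientation stream
const_stream <- function(ax, ay, az, n = 150, fs = 50) {
  accel_stream(data.frame(t = (seq_len(n) - 1) / fs, ax = ax, ay = ay, az = az),
               fs = fs)
}

# a stream holding arbitrary per-axis signals
signal_stream <- function(x, y = x, z = x, fs = 50) {
  n <- length(x)
  accel_stream(data.frame(t = (seq_len(n) - 1) / fs, ax = x, ay = y, az = z),
               fs = fs)
}

# well-separated 4-class clusters in two features
cluster_data <- function(n_per = 30, sd = 0.2, seed = 42) {
  set.seed(seed)
  centers <- c(0, 4, 8, 12)
  tibble::tibble(
    f1 = rnorm(4 * n_per, sd = sd) + rep(centers, each = n_per),
    f2 = rnorm(4 * n_per, sd = sd),
    label = factor(rep(posture_levels(), each = n_per),
                   levels = posture_levels()))
}

# standing calibration profile pointing along +z
unit_z_calibration <- function() {
  s <- const_stream(0, 0, 1)
  calibrate_standing(s)
}
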