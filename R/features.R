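# Sliding-window segmentation and the 13 time-domain feature families,
# computed per axis within each window.  One classification is emitted per
# window, so the window/step durations set the output rate of the pipeline.

FEATURE_FAMILIES <- c("MAV", "STD", "VAR", "MAX", "MIN", "RMS", "SSI",
                      "WENT", "SKEW", "KURT", "DAC", "SAC", "LEE")
SELECTED_FAMILIES <- c("MAV", "VAR", "DAC", "SAC", "KURT", "SKEW")
META_COLS <- c("t", "t_start", "label", "segment", "subject", "group")

#' The 13 time-domain feature families
#'
#' In fixed column order: mean absolute value (MAV), standard deviation
#' (STD), variance (VAR), maximum (MAX), minimum (MIN), root mean square
#' (RMS), simple squared integral (SSI), Shannon energy (wavelet) entropy
#' (WENT), skewness (SKEW), kurtosis (KURT), dynamic acceleration change
#' (DAC), static acceleration change (SAC) and log energy entropy (LEE).
#'
#' @return Character vector of family names.
#' @export
feature_families <- function() FEATURE_FAMILIES

#' The six feature families retained by L1 selection
#'
#' The pipeline's default working set: mean absolute value, variance,
#' dynamic and static acceleration change, kurtosis and skewness, per axis
#' (18 columns).  [lasso_select()] reproduces the selection procedure.
#'
#' @return Character vector of family names.
#' @export
selected_families <- function() SELECTED_FAMILIES

#' Sliding-window specification
#'
#' Defaults: 350 ms windows advanced in 50 ms steps.  Sample counts are
#' derived with a ceiling rule, `window_samples = ceiling(window_ms * fs /
#' 1000)`, so every window covers at least the nominal duration (350 ms at
#' 50 Hz is 17.5 samples, rounded up to 18; the 50 ms step becomes 3).
#'
#' @param window_ms Window duration in milliseconds (default 350).
#' @param step_ms Step (increment) in milliseconds (default 50).
#' @return A `window_spec` list.
#' @export
window_spec <- function(window_ms = 350, step_ms = 50) {
  if (window_ms <= 0 || step_ms <= 0) stop_config("Window and step must be positive.")
  if (step_ms > window_ms) stop_config("`step_ms` must not exceed `window_ms`.")
  structure(list(window_ms = window_ms, step_ms = step_ms),
            class = "window_spec")
}

window_samples <- function(spec, fs) {
  ws <- as.integer(ceiling(spec$window_ms * fs / 1000))
  ss <- as.integer(ceiling(spec$step_ms * fs / 1000))
  if (ws < 2) stop_config("Window spans fewer than 2 samples at this rate.")
  list(window = ws, step = max(ss, 1L))
}

#' Enumerate sliding windows over a stream
#'
#' @param stream An [accel_stream()].
#' @param spec A [window_spec()].
#' @return A tibble with one row per window: `window`, `start`, `end`
#'   (1-based sample indices, inclusive) and `t_start`.  A stream shorter
#'   than one window yields zero rows with a warning.
#' @export
#' @examples
#' s <- accel_stream(data.frame(t = (0:99) / 50, ax = 0, ay = 0, az = 1), fs = 50)
#' nrow(make_windows(s, window_spec()))  # 28
make_windows <- function(stream, spec = window_spec()) {
  fs <- stream_fs(stream)
  n <- nrow(stream)
  ws <- window_samples(spec, fs)
  empty <- tibble::tibble(window = integer(), start = integer(),
                          end = integer(), t_start = numeric())
  if (n < ws$window) {
    warn(sprintf("Stream of %d samples is shorter than one %d-sample window.",
                 n, ws$window))
    return(empty)
  }
  n_win <- (n - ws$window) %/% ws$step + 1L
  start <- (seq_len(n_win) - 1L) * ws$step + 1L
  tibble::tibble(window = seq_len(n_win), start = start,
                 end = start + ws$window - 1L, t_start = stream$t[start])
}

# Vectorized per-axis feature block.  A and S are n_windows x window_samples
# matrices of the dynamic (filtered) and static (gravity) signal.
feature_block <- function(A, S) {
  n <- ncol(A)
  mu <- rowMeans(A)
  msq <- rowMeans(A^2)
  VAR <- pmax(msq - mu^2, 0)          # population variance (1/N)
  STD <- sqrt(VAR)
  cols <- lapply(seq_len(ncol(A)), function(j) A[, j])
  MAX <- do.call(pmax, cols)
  MIN <- do.call(pmin, cols)
  RMS <- sqrt(msq)
  SSI <- msq * n
  # Shannon entropy of the window's normalised energy distribution
  P <- A^2 / SSI
  PL <- P * log(P)
  PL[P == 0] <- 0
  WENT <- -rowSums(PL)
  C <- A - mu
  m3 <- rowMeans(C^3)
  m4 <- rowMeans(C^4)
  degen <- STD < 1e-12
  SKEW <- ifelse(degen, 0, m3 / STD^3)
  KURT <- ifelse(degen, 0, m4 / STD^4)
  scols <- lapply(seq_len(ncol(S)), function(j) S[, j])
  SAC <- do.call(pmax, scols) - do.call(pmin, scols)
  LEE <- rowSums(log2(A^2 + 1e-12))
  tibble::tibble(MAV = rowMeans(abs(A)), STD = STD, VAR = VAR, MAX = MAX,
                 MIN = MIN, RMS = RMS, SSI = SSI, WENT = WENT, SKEW = SKEW,
                 KURT = KURT, DAC = MAX - MIN, SAC = SAC, LEE = LEE)
}

#' Time-domain features of a single window
#'
#' Low-level entry point used for real-time (window-at-a-time) operation and
#' for testing: computes the full 13-family feature vector for one window.
#'
#' @param dynamic An N x 3 numeric matrix (columns x, y, z) of the filtered
#'   window signal, N >= 2.
#' @param static An N x 3 matrix of the static (gravity) component for the
#'   same window; defaults to `dynamic`.
#' @return A named numeric vector of length 39 (`MAV_x`, `MAV_y`, ... in
#'   fixed family-major order).
#' @export
window_features <- function(dynamic, static = dynamic) {
  dynamic <- as.matrix(dynamic)
  static <- as.matrix(static)
  if (nrow(dynamic) < 2) {
    abort("Window too short: need at least 2 samples.",
          class = "posturekit_window_error")
  }
  stopifnot(ncol(dynamic) == 3, all(dim(static) == dim(dynamic)))
  axis_letter <- c("x", "y", "z")
  vals <- matrix(0, length(FEATURE_FAMILIES), 3,
                 dimnames = list(FEATURE_FAMILIES, axis_letter))
  n <- nrow(dynamic)
  for (i in 1:3) {
    a <- dynamic[, i]
    s <- static[, i]
    mu <- mean(a)
    msq <- mean(a^2)
    v <- max(msq - mu^2, 0)
    std <- sqrt(v)
    mx <- max(a)
    mn <- min(a)
    ssi <- msq * n
    p <- a^2 / ssi
    pl <- p * log(p)
    pl[p == 0] <- 0
    cdev <- a - mu
    degen <- std < 1e-12
    vals[, i] <- c(
      mean(abs(a)), std, v, mx, mn, sqrt(msq), ssi, -sum(pl),
      if (degen) 0 else mean(cdev^3) / std^3,
      if (degen) 0 else mean(cdev^4) / std^4,
      mx - mn, max(s) - min(s), sum(log2(a^2 + 1e-12)))
  }
  out <- as.vector(t(vals))
  names(out) <- as.vector(t(outer(FEATURE_FAMILIES, axis_letter,
                                  paste, sep = "_")))
  out
}

# majority vote along window rows of an integer label matrix; ties go to the
# label occurring earliest inside the window
window_majority <- function(L, n_levels) {
  counts <- vapply(seq_len(n_levels), function(k) rowSums(L == k),
                   numeric(nrow(L)))
  counts <- matrix(counts, nrow = nrow(L))
  top <- max.col(counts, ties.method = "first")
  maxc <- counts[cbind(seq_len(nrow(L)), top)]
  ties <- rowSums(counts == maxc) > 1
  for (r in which(ties)) {
    cand <- which(counts[r, ] == maxc[r])
    first_pos <- vapply(cand, function(k) match(k, L[r, ]), integer(1))
    top[r] <- cand[which.min(first_pos)]
  }
  top
}

#' Build the per-window feature matrix of a stream
#'
#' Segments a filtered stream into sliding windows and computes the
#' time-domain features per axis, in the fixed family-major column order
#' (`MAV_x`, `MAV_y`, `MAV_z`, `STD_x`, ...).  The static component for the
#' SAC feature is extracted internally with [compute_static_component()].
#' When the stream carries a `label` column, each window is labelled by the
#' majority label of its samples (ties resolved towards the label occurring
#' earlier in the window); `segment` and `subject` metadata propagate the
#' same way.
#'
#' @param stream A filtered [accel_stream()] in g units.
#' @param spec A [window_spec()].
#' @param layout `"selected"` (default, the 6 retained families, 18 columns)
#'   or `"full"` (13 families, 39 columns).
#' @param static_cutoff_hz Cutoff for the static component (default 0.5 Hz).
#' @param static_order Order of the static low-pass (default 2).
#' @return A tibble: `t_start`, feature columns, then any propagated
#'   metadata (`label`, `segment`, `subject`).
#' @export
posture_features <- function(stream, spec = window_spec(),
                             layout = c("selected", "full"),
                             static_cutoff_hz = 0.5, static_order = 2) {
  layout <- match.arg(layout)
  fams <- if (layout == "full") FEATURE_FAMILIES else SELECTED_FAMILIES
  wins <- make_windows(stream, spec)
  axis_letter <- c("x", "y", "z")
  feat_names <- as.vector(t(outer(fams, axis_letter, paste, sep = "_")))
  if (nrow(wins) == 0) {
    out <- c(list(t_start = numeric(0)),
             setNames(rep(list(numeric(0)), length(feat_names)), feat_names))
    return(tibble::as_tibble(out))
  }
  static <- compute_static_component(stream, cutoff_hz = static_cutoff_hz,
                                     order = static_order)
  ws <- window_samples(spec, stream_fs(stream))
  idx <- outer(wins$start, 0:(ws$window - 1L), `+`)
  blocks <- lapply(1:3, function(i) {
    A <- matrix(stream[[AXES[i]]][idx], nrow = nrow(wins))
    S <- matrix(static[[AXES[i]]][idx], nrow = nrow(wins))
    feature_block(A, S)
  })
  out <- tibble::tibble(t_start = wins$t_start)
  for (fam in fams) {
    for (i in 1:3) {
      out[[paste0(fam, "_", axis_letter[i])]] <- blocks[[i]][[fam]]
    }
  }
  if ("label" %in% names(stream)) {
    lab <- stream$label
    L <- matrix(as.integer(lab)[idx], nrow = nrow(wins))
    out$label <- factor(levels(lab)[window_majority(L, nlevels(lab))],
                        levels = levels(lab))
  }
  for (meta in c("segment", "subject")) {
    if (meta %in% names(stream)) {
      v <- as.factor(stream[[meta]])
      L <- matrix(as.integer(v)[idx], nrow = nrow(wins))
      maj <- levels(v)[window_majority(L, nlevels(v))]
      out[[meta]] <- if (is.numeric(stream[[meta]])) as.numeric(maj) else maj
    }
  }
  out
}

#' Write / read a feature matrix as CSV
#'
#' @param features A feature tibble from [posture_features()].
#' @param path File path.
#' @return The path (write) or the feature tibble (read).
#' @export
write_features_csv <- function(features, path) {
  readr::write_csv(features, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_features_csv
#' @export
read_features_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if ("label" %in% names(df)) df$label <- as_posture(df$label)
  df
}

feature_cols <- function(data) {
  num <- vapply(data, is.numeric, logical(1))
  setdiff(names(data)[num], META_COLS)
}
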