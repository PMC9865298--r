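# Confusion-matrix bookkeeping and the classification metrics.  The
# multiclass counts are reduced one-vs-rest per class: with class c taken as
# positive, TP are windows of c predicted c, FP windows of other classes
# predicted c, FN windows of c predicted otherwise, TN the rest.

#' Confusion matrix of true versus predicted postures
#'
#' @param truth,estimate Equal-length label vectors (factor or character).
#' @param levels Class levels; defaults to the union of levels observed,
#'   ordered as in `posture_levels()` when applicable.
#' @return A `posture_confusion` object: an integer matrix indexed
#'   `[true, predicted]`.
#' @export
posture_confusion <- function(truth, estimate, levels = NULL) {
  if (length(truth) != length(estimate)) {
    stop_validation(sprintf(
      "Length mismatch: %d true vs %d predicted labels.",
      length(truth), length(estimate)))
  }
  if (is.null(levels)) {
    obs <- union(levels(as.factor(truth)), levels(as.factor(estimate)))
    levels <- if (all(obs %in% posture_levels())) {
      intersect(posture_levels(), obs)
    } else sort(obs)
  }
  truth <- factor(as.character(truth), levels = levels)
  estimate <- factor(as.character(estimate), levels = levels)
  m <- table(true = truth, predicted = estimate)
  structure(unclass(m), class = "posture_confusion")
}

#' @export
print.posture_confusion <- function(x, ...) {
  cat("<posture_confusion> (rows = true, cols = predicted)\n")
  print(unclass(x))
  invisible(x)
}

# per-class one-vs-rest counts
ovr_counts <- function(cm) {
  total <- sum(cm)
  classes <- rownames(cm)
  tp <- diag(cm)
  fn <- rowSums(cm) - tp
  fp <- colSums(cm) - tp
  tn <- total - tp - fn - fp
  tibble::tibble(class = classes, tp = as.integer(tp), tn = as.integer(tn),
                 fp = as.integer(fp), fn = as.integer(fn))
}

#' @export
tidy.posture_confusion <- function(x, ...) ovr_counts(x)

safe_ratio <- function(num, den, what) {
  out <- ifelse(den == 0, 0, num / den)
  if (any(den == 0)) {
    warn(paste0(what, " undefined (0/0) for some class(es); reported as 0."))
  }
  out
}

#' Classification metrics from a confusion matrix
#'
#' Overall accuracy is the fraction of correctly classified windows
#' (the trace over the total, equivalently the one-vs-rest
#' `(TP + TN) / (TP + TN + FP + FN)` averaged over classes).  Precision
#' `TP / (TP + FP)`, recall `TP / (TP + FN)` and F1
#' `2 TP / (2 TP + FP + FN)` are computed per class and macro-averaged.
#' Degenerate 0/0 ratios are reported as 0 with a warning.
#'
#' @param cm A `posture_confusion` (or plain square count matrix).
#' @return A `posture_metrics` object: `$overall` (one-row tibble with
#'   `accuracy`, `precision`, `recall`, `f1`) and `$by_class`.
#' @export
confusion_metrics <- function(cm) {
  cm <- as.matrix(unclass(cm))
  total <- sum(cm)
  if (total == 0) stop_validation("Empty confusion matrix: no evaluated windows.")
  counts <- ovr_counts(cm)
  pr <- safe_ratio(counts$tp, counts$tp + counts$fp, "Precision")
  re <- safe_ratio(counts$tp, counts$tp + counts$fn, "Recall")
  f1 <- safe_ratio(2 * counts$tp, 2 * counts$tp + counts$fp + counts$fn, "F1")
  by_class <- dplyr::mutate(counts,
                            accuracy = (counts$tp + counts$tn) / total,
                            precision = pr, recall = re, f1 = f1)
  overall <- tibble::tibble(
    accuracy = sum(diag(cm)) / total,
    precision = mean(pr), recall = mean(re), f1 = mean(f1))
  structure(list(overall = overall, by_class = by_class,
                 confusion = structure(cm, class = "posture_confusion")),
            class = "posture_metrics")
}

#' @export
print.posture_metrics <- function(x, ...) {
  cat("<posture_metrics>\n")
  cat(sprintf("  accuracy %.4f | macro precision %.4f | recall %.4f | F1 %.4f\n",
              x$overall$accuracy, x$overall$precision,
              x$overall$recall, x$overall$f1))
  invisible(x)
}

#' @export
tidy.posture_metrics <- function(x, ...) {
  x$by_class[c("class", "precision", "recall", "f1", "accuracy")]
}

#' @export
glance.posture_metrics <- function(x, ...) x$overall

#' Downsample a stream by an integer factor
#'
#' Keeps every `fs / target_fs`-th sample.  Meant to be applied after the
#' 10 Hz low-pass, which already acts as the anti-alias filter for the
#' 50 to 25 Hz experiment (10 Hz < 12.5 Hz Nyquist).
#'
#' @param stream An [accel_stream()].
#' @param target_fs Target rate in Hz; must divide `fs` exactly.
#' @return The decimated stream with `fs = target_fs`.
#' @export
downsample_stream <- function(stream, target_fs) {
  decimate_stream(stream, target_fs)
}

#' Downsample a whole cohort with anti-alias filtering
#'
#' Applies the main low-pass per subject (its 10 Hz cutoff sits below the
#' 12.5 Hz Nyquist frequency of the 25 Hz target, so it doubles as the
#' anti-alias filter) and then decimates each stream.
#'
#' @param cohort A stacked cohort tibble from [simulate_cohort()].
#' @param target_fs Target rate in Hz.
#' @param cutoff_hz,order Anti-alias low-pass design (defaults 10 Hz,
#'   order 8).
#' @return The decimated cohort tibble with updated `fs` attribute.
#' @export
downsample_cohort <- function(cohort, target_fs, cutoff_hz = 10, order = 8) {
  streams <- cohort_streams(cohort)
  out <- dplyr::bind_rows(lapply(streams, function(st) {
    st <- lowpass_filter(st, cutoff_hz = cutoff_hz, order = order)
    tibble::as_tibble(decimate_stream(st, target_fs))
  }))
  attr(out, "fs") <- target_fs
  attr(out, "units") <- stream_units(cohort)
  out
}

decimate_stream <- function(stream, target_fs) {
  fs <- stream_fs(stream)
  ratio <- fs / target_fs
  if (abs(ratio - round(ratio)) > 1e-9 || ratio < 1) {
    stop_config(sprintf("`target_fs` (%g) must divide fs (%g) exactly.",
                        target_fs, fs))
  }
  keep <- seq(1, nrow(stream), by = as.integer(round(ratio)))
  out <- tibble::as_tibble(stream)[keep, , drop = FALSE]
  accel_stream(out, fs = target_fs, units = stream_units(stream),
               validate = FALSE)
}
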