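# The 10-fold evaluation protocol: the data are split into 10 disjoint
# folds; in each repetition 8 folds train (80%), one fold is held out for
# validation (10%) and one for testing (10%).  By default fold assignment is
# grouped: all windows from the same contiguous posture bout (one subject's
# uninterrupted segment) land in the same fold, so overlapping windows never
# straddle the train/test boundary.

# stratified (per-class) round-robin fold assignment of rows
stratified_folds <- function(y, folds, seed) {
  fold_of <- integer(length(y))
  set.seed(as.integer(seed))
  nxt <- 0L
  for (cl in levels(y)) {
    idx <- which(y == cl)
    if (length(idx) < folds) {
      stop_config(sprintf(
        "Class '%s' has %d rows, fewer than %d folds; cannot stratify.",
        cl, length(idx), folds))
    }
    idx <- sample(idx)
    # continue the round-robin across classes so fold sizes stay balanced
    fold_of[idx] <- (nxt + seq_along(idx) - 1L) %% folds + 1L
    nxt <- nxt + length(idx)
  }
  fold_of
}

# Grouped stratified assignment: whole groups go to folds.  Within each
# class, groups sharing a source prefix (the part of the id before the last
# ':', i.e. the subject of a 'subject:segment' bout id) are interleaved
# before the round-robin, so one subject's repeated bouts of a posture are
# spread over different folds instead of piling into one; every fold still
# sees every class and no group is ever split.
grouped_folds <- function(y, groups, folds, seed) {
  groups <- as.character(groups)
  tab <- tibble::tibble(group = groups, y = y)
  per_group <- dplyr::summarise(
    dplyr::group_by(tab, .data$group),
    class = names(which.max(table(.data$y))), .groups = "drop")
  per_group$source <- sub(":[^:]*$", "", per_group$group)
  set.seed(as.integer(seed))
  fold_of_group <- setNames(integer(nrow(per_group)), per_group$group)
  nxt <- 0L
  for (cl in sort(unique(per_group$class))) {
    cl_groups <- per_group$group[per_group$class == cl]
    by_source <- split(cl_groups, per_group$source[per_group$class == cl])
    by_source <- by_source[sample(length(by_source))]
    by_source <- lapply(by_source, function(g) {
      if (length(g) > 1) sample(g) else g
    })
    interleaved <- unlist(lapply(seq_len(max(lengths(by_source))), function(j) {
      unlist(lapply(by_source, function(g) if (j <= length(g)) g[j]))
    }), use.names = FALSE)
    fold_of_group[interleaved] <- (nxt + seq_along(interleaved) - 1L) %% folds + 1L
    nxt <- nxt + length(interleaved)
  }
  unname(fold_of_group[groups])
}

#' Build a cross-validation plan
#'
#' @param labels Class labels, one per row.
#' @param groups Optional group ids (windows sharing a group are never
#'   separated across folds).
#' @param folds Number of folds (default 10).
#' @param seed Shuffling seed.
#' @return A `cv_plan`: integer fold per row plus a roles table listing, for
#'   each repetition, the test and validation fold.
#' @export
cv_plan <- function(labels, groups = NULL, folds = 10, seed = 0L) {
  y <- droplevels(as.factor(labels))
  fold_of <- if (is.null(groups)) {
    stratified_folds(y, folds, seed)
  } else {
    grouped_folds(y, groups, folds, seed)
  }
  roles <- tibble::tibble(
    repetition = seq_len(folds),
    test_fold = seq_len(folds),
    validation_fold = seq_len(folds) %% folds + 1L)
  structure(list(fold_of = fold_of, folds = folds, seed = as.integer(seed),
                 grouped = !is.null(groups), roles = roles),
            class = "cv_plan")
}

#' Cross-validated evaluation of a classifier
#'
#' Runs the 10-repetition protocol: per repetition the model is fitted on
#' the 8 training folds (80% of the data), the validation fold is held out
#' (available for model selection; unused by the fixed-hyperparameter
#' defaults) and the test fold is scored.  Metrics are aggregated as mean
#' and standard deviation over the test folds; a pooled confusion matrix
#' over all test predictions is also returned.  Deterministic given `seed`.
#'
#' @param data A labelled feature tibble.
#' @param config A `model_config`.
#' @param folds Number of folds (default 10).
#' @param seed Seed for fold shuffling (the model keeps its own config seed).
#' @param label Label column name.
#' @param group Grouping column name for leakage-safe folds; defaults to
#'   `"group"` when present, else `NULL` (fully random stratified rows).
#'   Pass `NULL` explicitly to force ungrouped folds.
#' @return A `posture_cv` object; see [tidy.posture_cv()] /
#'   [glance.posture_cv()].
#' @export
cross_validate <- function(data, config, folds = 10, seed = 0L,
                           label = "label",
                           group = if ("group" %in% names(data)) "group") {
  y <- droplevels(as.factor(data[[label]]))
  groups <- if (!is.null(group)) data[[group]]
  plan <- cv_plan(y, groups, folds = folds, seed = seed)
  fold_of <- plan$fold_of
  fold_rows <- list()
  pooled <- NULL
  for (r in seq_len(folds)) {
    test_f <- plan$roles$test_fold[r]
    val_f <- plan$roles$validation_fold[r]
    is_test <- fold_of == test_f
    is_val <- fold_of == val_f
    train <- data[!is_test & !is_val, , drop = FALSE]
    test <- data[is_test, , drop = FALSE]
    model <- fit_posture(train, config, label = label)
    pred <- predict(model, test)
    cm <- posture_confusion(test[[label]], pred, levels = levels(y))
    met <- confusion_metrics(cm)
    pooled <- if (is.null(pooled)) unclass(cm) else pooled + unclass(cm)
    fold_rows[[r]] <- tibble::tibble(
      fold = r, n_train = nrow(train), n_validation = sum(is_val),
      n_test = nrow(test),
      accuracy = met$overall$accuracy, precision = met$overall$precision,
      recall = met$overall$recall, f1 = met$overall$f1)
  }
  per_fold <- dplyr::bind_rows(fold_rows)
  summary <- tidyr::pivot_longer(
    per_fold[c("accuracy", "precision", "recall", "f1")],
    dplyr::everything(), names_to = "metric", values_to = "value")
  summary <- dplyr::summarise(dplyr::group_by(summary, .data$metric),
                              mean = mean(.data$value), sd = sd(.data$value),
                              .groups = "drop")
  summary <- summary[match(c("accuracy", "precision", "recall", "f1"),
                           summary$metric), ]
  structure(list(per_fold = per_fold, summary = summary,
                 confusion = structure(pooled, class = "posture_confusion"),
                 plan = plan, config = config),
            class = "posture_cv")
}

#' @export
print.posture_cv <- function(x, ...) {
  cat(sprintf("<posture_cv %s: %d folds%s>\n", toupper(x$config$kind),
              x$plan$folds, if (x$plan$grouped) ", grouped" else ""))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-9s %.4f +/- %.4f\n", s$metric[i], s$mean[i], s$sd[i]))
  }
  invisible(x)
}

#' Tidy a cross-validation result
#'
#' `tidy()` returns the per-fold metric table; `glance()` a one-row summary
#' with mean and standard deviation of each metric over the test folds.
#'
#' @param x A `posture_cv`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.posture_cv <- function(x, ...) x$per_fold

#' @rdname tidy.posture_cv
#' @export
glance.posture_cv <- function(x, ...) {
  s <- x$summary
  out <- tibble::tibble(model = x$config$kind, folds = x$plan$folds)
  for (i in seq_len(nrow(s))) {
    out[[s$metric[i]]] <- s$mean[i]
    out[[paste0(s$metric[i], "_sd")]] <- s$sd[i]
  }
  out
}
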