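# L1-penalised feature-family selection.  The selection target is a posture
# class, so the penalised model is a multinomial linear classifier; a feature
# family survives if any of its per-axis, per-class coefficients is non-zero
# after standardisation.

#' Lasso feature-family selection
#'
#' Fits an L1-penalised multinomial linear model on the standardised feature
#' columns and aggregates coefficient magnitudes to the family level (the
#' maximum absolute coefficient over classes and axes).  Families whose
#' aggregate weight exceeds `1e-8` are selected.
#'
#' @param features A labelled feature tibble (from [posture_features()] with
#'   `layout = "full"`, or any tibble with `<FAMILY>_<axis>` columns).
#' @param penalty The L1 penalty (glmnet `lambda`), default 0.01.
#' @param label Name of the label column (default `"label"`).
#' @param seed Seed (the fit itself is deterministic; kept for contract).
#' @return A `posture_selection` object with a per-family weight table.
#' @export
lasso_select <- function(features, penalty = 0.01, label = "label", seed = 0L) {
  if (!label %in% names(features)) stop_validation("No label column found.")
  y <- droplevels(as.factor(features[[label]]))
  if (nlevels(y) < 2) {
    abort("Feature selection needs at least two classes.",
          class = "posturekit_degenerate_labels_error")
  }
  cols <- feature_cols(features)
  if (length(cols) == 0) stop_validation("No numeric feature columns found.")
  x <- as.matrix(features[cols])
  if (anyNA(x)) stop_validation("Feature matrix contains missing values.")
  set.seed(as.integer(seed))
  fit <- glmnet::glmnet(x, y, family = "multinomial", lambda = penalty,
                        standardize = TRUE)
  coefs <- glmnet::coef.glmnet(fit, s = penalty)
  per_col <- rep(0, length(cols))
  names(per_col) <- cols
  for (cl in names(coefs)) {
    b <- as.numeric(coefs[[cl]])[-1]  # drop intercept
    per_col <- pmax(per_col, abs(b))
  }
  fam_of <- sub("_[xyz]$", "", cols)
  fams <- unique(fam_of)
  weight <- vapply(fams, function(f) max(per_col[fam_of == f]), numeric(1))
  tab <- tibble::tibble(family = fams, weight = unname(weight),
                        selected = unname(weight) > 1e-8)
  tab <- dplyr::arrange(tab, dplyr::desc(.data$weight))
  if (!any(tab$selected)) {
    stop_config("Penalty too large: no feature family survived selection.")
  }
  structure(list(families = tab,
                 selected_families = tab$family[tab$selected],
                 penalty = penalty),
            class = "posture_selection")
}

#' @export
print.posture_selection <- function(x, ...) {
  cat(sprintf("<posture_selection: %d of %d families at penalty %g>\n",
              length(x$selected_families), nrow(x$families), x$penalty))
  cat("  selected:", paste(x$selected_families, collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.posture_selection <- function(x, ...) x$families
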