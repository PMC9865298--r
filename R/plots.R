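# ggplot2 views of the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_tile geom_text
#'   geom_point geom_hline facet_grid labs scale_fill_gradient theme_minimal
NULL

#' Plot an acceleration stream
#'
#' One panel per axis; when the stream is labelled the trace is coloured by
#' posture.
#'
#' @param object An [accel_stream()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.accel_stream <- function(object, ...) {
  df <- tidyr::pivot_longer(tibble::as_tibble(object), dplyr::all_of(AXES),
                            names_to = "axis", values_to = "acceleration_g")
  p <- ggplot(df, aes(x = .data$t, y = .data$acceleration_g))
  p <- if ("label" %in% names(df)) {
    p + geom_line(aes(colour = .data$label, group = 1), linewidth = 0.3)
  } else {
    p + geom_line(linewidth = 0.3)
  }
  p + facet_grid(rows = ggplot2::vars(.data$axis)) +
    labs(x = "time (s)", y = "acceleration (g)", colour = "posture") +
    theme_minimal()
}

#' Plot a confusion matrix
#'
#' @param object A `posture_confusion`.
#' @param ... Unused.
#' @return A ggplot tile map with counts.
#' @export
autoplot.posture_confusion <- function(object, ...) {
  df <- as.data.frame(as.table(unclass(object)))
  names(df) <- c("true", "predicted", "n")
  ggplot(df, aes(x = .data$predicted, y = .data$true, fill = .data$n)) +
    geom_tile() +
    geom_text(aes(label = .data$n), size = 3) +
    scale_fill_gradient(low = "white", high = "steelblue") +
    labs(x = "predicted", y = "true") +
    theme_minimal()
}

#' Plot per-fold cross-validation accuracies
#'
#' @param object A `posture_cv`.
#' @param ... Unused.
#' @return A ggplot of fold accuracies with the mean as a dashed line.
#' @export
autoplot.posture_cv <- function(object, ...) {
  df <- object$per_fold
  m <- object$summary$mean[object$summary$metric == "accuracy"]
  ggplot(df, aes(x = factor(.data$fold), y = .data$accuracy)) +
    geom_point() +
    geom_hline(yintercept = m, linetype = "dashed") +
    labs(x = "fold", y = "test accuracy",
         title = sprintf("%s: mean accuracy %.3f",
                         toupper(object$config$kind), m)) +
    theme_minimal()
}

#' @export
plot.accel_stream <- function(x, ...) print(autoplot(x, ...))
#' @export
plot.posture_confusion <- function(x, ...) print(autoplot(x, ...))
#' @export
plot.posture_cv <- function(x, ...) print(autoplot(x, ...))
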