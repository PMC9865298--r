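# End-to-end wiring: simulate (or load) -> low-pass filter -> standing
# calibration -> windowed feature extraction -> cross-validated
# classification, mirroring the block order of the processing framework.

#' Filter a cohort and extract per-window features
#'
#' Applies the main low-pass per subject, extracts windowed features
#' (windows never span subjects) and attaches a leakage grouping column
#' `group` identifying the contiguous posture bout
#' (`subject:segment`) each window came from.
#'
#' @param cohort A stacked cohort tibble from [simulate_cohort()].
#' @param spec A [window_spec()].
#' @param layout `"selected"` or `"full"`.
#' @param cutoff_hz,order Main low-pass parameters.
#' @param static_cutoff_hz,static_order Static-component low-pass parameters.
#' @param fs Sampling frequency; defaults to the cohort attribute.
#' @return A labelled feature tibble with `subject` and `group` columns.
#' @export
cohort_features <- function(cohort, spec = window_spec(),
                            layout = c("selected", "full"),
                            cutoff_hz = 10, order = 8,
                            static_cutoff_hz = 0.5, static_order = 2,
                            fs = attr(cohort, "fs")) {
  layout <- match.arg(layout)
  streams <- cohort_streams(cohort, fs = fs)
  feats <- lapply(streams, function(st) {
    st <- lowpass_filter(st, cutoff_hz = cutoff_hz, order = order)
    posture_features(st, spec = spec, layout = layout,
                     static_cutoff_hz = static_cutoff_hz,
                     static_order = static_order)
  })
  out <- dplyr::bind_rows(feats)
  if (all(c("subject", "segment") %in% names(out))) {
    out$group <- paste0(out$subject, ":", out$segment)
  }
  out
}

#' Pipeline configuration
#'
#' Aggregates every tunable constant of the pipeline into one serializable
#' object.  Defaults are the shipped operating point: 50 Hz sampling, 350 /
#' 50 ms windows, order-8 10 Hz low-pass, 0.5 Hz static cutoff, 0.15 g /
#' 0.05 g calibration tolerances, the six selected feature families, the
#' three tuned classifiers and 10-fold grouped cross-validation.
#'
#' @param fs Sampling frequency (Hz).
#' @param window_ms,step_ms Sliding-window duration and step (ms).
#' @param filter_order,cutoff_hz Main low-pass design.
#' @param static_cutoff_hz,static_order Static-component low-pass design.
#' @param gravity_axis Device axis carrying gravity when standing.
#' @param tolerance_g,static_std_max_g Calibration tolerances (g).
#' @param layout Feature layout, `"selected"` or `"full"`.
#' @param models Named list of `model_config`s to evaluate.
#' @param folds Cross-validation folds.
#' @param n_subjects Cohort size for simulation.
#' @param seed Master seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(fs = 50, window_ms = 350, step_ms = 50,
                            filter_order = 8, cutoff_hz = 10,
                            static_cutoff_hz = 0.5, static_order = 2,
                            gravity_axis = "z", tolerance_g = 0.15,
                            static_std_max_g = 0.05,
                            layout = "selected",
                            models = list(rf = rf_config(), dt = dt_config(),
                                          knn = knn_config()),
                            folds = 10, n_subjects = 7, seed = 0L) {
  if (cutoff_hz >= fs / 2) stop_config("`cutoff_hz` must be below fs/2.")
  if (static_cutoff_hz >= cutoff_hz) {
    stop_config("`static_cutoff_hz` must be below the main cutoff.")
  }
  structure(list(fs = fs, window_ms = window_ms, step_ms = step_ms,
                 filter_order = filter_order, cutoff_hz = cutoff_hz,
                 static_cutoff_hz = static_cutoff_hz,
                 static_order = static_order,
                 gravity_axis = gravity_axis, tolerance_g = tolerance_g,
                 static_std_max_g = static_std_max_g, layout = layout,
                 models = models, folds = folds, n_subjects = n_subjects,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Serialize / restore a pipeline configuration
#'
#' @param config A `pipeline_config`.
#' @param path YAML file path.
#' @return `write_pipeline_config()` returns `path` invisibly;
#'   `read_pipeline_config()` the restored config.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  obj <- unclass(config)
  obj$models <- lapply(config$models, unclass)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  obj <- yaml::read_yaml(path)
  obj$models <- lapply(obj$models, function(m) {
    kind <- m$kind
    m$kind <- NULL
    seed <- m$seed %||% 0L
    m$seed <- NULL
    switch(kind,
           rf = do.call(rf_config, c(m[c("num_trees", "max_depth")],
                                     list(seed = seed))),
           dt = do.call(dt_config, c(m["max_depth"], list(seed = seed))),
           knn = do.call(knn_config, c(m[c("k", "p")], list(seed = seed))),
           stop_config(paste0("Unknown model kind in config: ", kind)))
  })
  do.call(pipeline_config, obj)
}

#' Run the full recognition pipeline on synthetic data
#'
#' Executes the processing chain in order: simulate a cohort, verify the
#' standing calibration of every subject on their first standing bout,
#' low-pass filter, extract windowed features, and cross-validate every
#' configured classifier.  Each stage is logged; stage failures surface
#' with the stage name.
#'
#' @param config A [pipeline_config()].
#' @param cohort Optional pre-built cohort tibble; simulated when `NULL`.
#' @param quiet Suppress stage logging.
#' @return A `posture_pipeline` object: the calibrations, the feature
#'   matrix, and one `posture_cv` per configured model.
#' @export
run_pipeline <- function(config = pipeline_config(), cohort = NULL,
                         quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) inform(sprintf(...))
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(force(expr), error = function(e) {
      abort(paste0("Pipeline stage '", name, "' failed: ",
                   conditionMessage(e)), parent = e)
    })
    say("[%s] done in %.2f s", name, proc.time()[["elapsed"]] - t0)
    out
  }

  cohort <- stage("simulate", cohort %||% simulate_cohort(
    n_subjects = config$n_subjects, seed = config$seed, fs = config$fs))

  calibrations <- stage("calibrate", {
    # prefer the dedicated calibration holds; fall back to the first
    # standing bout for cohorts loaded without per-subject parameters
    cal_streams <- if (!is.null(attr(cohort, "subjects"))) {
      cohort_calibration_streams(cohort)
    } else {
      lapply(cohort_streams(cohort, fs = config$fs), function(st) {
        standing <- st[!is.na(st$label) & st$label == "standing", ,
                       drop = FALSE]
        if (nrow(standing) == 0) {
          stop_calibration("No standing bout available for calibration.")
        }
        first_seg <- standing[standing$segment == standing$segment[1], ,
                              drop = FALSE]
        accel_stream(first_seg, fs = config$fs, validate = FALSE)
      })
    }
    lapply(cal_streams, function(st) {
      st <- lowpass_filter(st, cutoff_hz = config$cutoff_hz,
                           order = config$filter_order)
      calibrate_standing(st, gravity_axis = config$gravity_axis,
                         tolerance_g = config$tolerance_g,
                         static_std_max_g = config$static_std_max_g)
    })
  })

  features <- stage("features", cohort_features(
    cohort, spec = window_spec(config$window_ms, config$step_ms),
    layout = config$layout, cutoff_hz = config$cutoff_hz,
    order = config$filter_order,
    static_cutoff_hz = config$static_cutoff_hz,
    static_order = config$static_order, fs = config$fs))

  reports <- stage("classification", {
    lapply(config$models, function(m) {
      cross_validate(features, m, folds = config$folds, seed = config$seed)
    })
  })

  structure(list(config = config, calibrations = calibrations,
                 features = features, reports = reports),
            class = "posture_pipeline")
}

#' @export
print.posture_pipeline <- function(x, ...) {
  cat(sprintf("<posture_pipeline: %d windows, %d subjects, %d model(s)>\n",
              nrow(x$features), length(x$calibrations), length(x$reports)))
  for (nm in names(x$reports)) print(x$reports[[nm]])
  invisible(x)
}

#' One-row-per-model summary of a pipeline run
#'
#' @param x A `posture_pipeline`.
#' @param ... Unused.
#' @return A tibble with one row per classifier (mean metrics over folds).
#' @export
glance.posture_pipeline <- function(x, ...) {
  dplyr::bind_rows(lapply(x$reports, glance))
}
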