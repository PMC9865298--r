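# The three classifiers compared by the pipeline, each behind a common
# config/fit/predict surface.  Defaults are the grid-search optima:
#   RF : 25 gini trees of depth <= 30        (ranger backend)
#   DT : single gini tree of depth <= 19     (rpart backend)
#   KNN: k = 13, Minkowski p = 2, votes weighted by inverse distance,
#        features standardised with training statistics (in-package backend)

#' Classifier configurations
#'
#' Constructors for the model configurations understood by [fit_posture()].
#' Defaults are the tuned hyperparameters the pipeline ships with; pass a
#' different `seed` for independent stochastic replicates (only the random
#' forest is stochastic).
#'
#' @param num_trees Number of trees in the forest (default 25).
#' @param max_depth Maximum tree depth (RF default 30, DT default 19).
#' @param k Number of neighbours (default 13).
#' @param p Minkowski exponent (default 2, Euclidean).
#' @param seed Integer seed used at fit time.
#' @return A `model_config` list with elements `kind`, hyperparameters and
#'   `seed`.
#' @export
rf_config <- function(num_trees = 25, max_depth = 30, seed = 0L) {
  new_model_config("rf", list(num_trees = as.integer(num_trees),
                              max_depth = as.integer(max_depth),
                              criterion = "gini"), seed)
}

#' @rdname rf_config
#' @export
dt_config <- function(max_depth = 19, seed = 0L) {
  new_model_config("dt", list(max_depth = as.integer(max_depth),
                              criterion = "gini"), seed)
}

#' @rdname rf_config
#' @export
knn_config <- function(k = 13, p = 2, seed = 0L) {
  new_model_config("knn", list(k = as.integer(k), p = p,
                               weights = "distance"), seed)
}

new_model_config <- function(kind, params, seed) {
  structure(c(list(kind = kind), params, list(seed = as.integer(seed))),
            class = "model_config")
}

#' @export
print.model_config <- function(x, ...) {
  hp <- x[setdiff(names(x), c("kind", "seed"))]
  cat(sprintf("<model_config %s: %s; seed %d>\n", toupper(x$kind),
              paste(names(hp), unlist(hp), sep = "=", collapse = ", "),
              x$seed))
  invisible(x)
}

#' Fit a posture classifier
#'
#' Trains the configured model on the numeric feature columns of `data`
#' (every numeric column except window/stream metadata such as `t_start`,
#' `subject`, `segment`, `group`).  The fitted object stores the feature
#' column schema and the classes seen, and refuses prediction inputs that do
#' not carry the same columns.
#'
#' @param data A labelled feature tibble.
#' @param config A `model_config` from [rf_config()], [dt_config()] or
#'   [knn_config()].
#' @param label Name of the label column (default `"label"`).
#' @return A `posture_model`.
#' @export
fit_posture <- function(data, config, label = "label") {
  stopifnot(inherits(config, "model_config"))
  if (!label %in% names(data)) stop_validation("No label column found.")
  y <- droplevels(as.factor(data[[label]]))
  if (nlevels(y) < 2) {
    abort("Training needs at least two classes.",
          class = "posturekit_degenerate_labels_error")
  }
  cols <- feature_cols(data)
  if (length(cols) == 0) stop_validation("No numeric feature columns found.")
  x <- as.matrix(data[cols])
  if (anyNA(x)) stop_validation("Feature matrix contains missing values.")

  set.seed(config$seed)
  fit <- switch(config$kind,
    rf = {
      df <- data.frame(x, .posture = y, check.names = FALSE)
      # ranger treats seed 0 as "unseeded"; shift to keep 0 deterministic
      ranger::ranger(dependent.variable.name = ".posture", data = df,
                     num.trees = config$num_trees,
                     max.depth = config$max_depth,
                     splitrule = "gini", classification = TRUE,
                     seed = config$seed + 1L, num.threads = 1,
                     verbose = FALSE)
    },
    dt = {
      df <- data.frame(x, .posture = y, check.names = FALSE)
      tree <- rpart::rpart(.posture ~ ., data = df, method = "class",
                           parms = list(split = "gini"),
                           control = rpart::rpart.control(
                             maxdepth = config$max_depth, cp = 0,
                             minsplit = 2, minbucket = 1, xval = 0))
      attr(tree, "flat") <- dt_flatten(tree)
      tree
    },
    knn = {
      if (config$k > nrow(x)) {
        stop_config(sprintf("k = %d exceeds the %d training samples.",
                            config$k, nrow(x)))
      }
      knn_fit(x, y, k = config$k, p = config$p)
    },
    stop_config(paste0("Unknown model kind: ", config$kind))
  )
  structure(list(config = config, fit = fit, schema = cols,
                 classes = levels(y), n_train = nrow(x)),
            class = "posture_model")
}

#' @export
print.posture_model <- function(x, ...) {
  cat(sprintf("<posture_model %s: %d features, %d training windows, classes: %s>\n",
              toupper(x$config$kind), length(x$schema), x$n_train,
              paste(x$classes, collapse = ", ")))
  invisible(x)
}

#' Predict posture labels
#'
#' @param object A `posture_model`.
#' @param newdata A feature tibble carrying at least the columns the model
#'   was trained on (extra columns and column order are ignored).
#' @param ... Unused.
#' @return A factor of predicted postures, one per row of `newdata`.
#' @export
predict.posture_model <- function(object, newdata, ...) {
  missing_cols <- setdiff(object$schema, names(newdata))
  if (length(missing_cols) > 0) {
    abort(paste0("Prediction input is missing feature column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "posturekit_schema_error")
  }
  x <- as.matrix(tibble::as_tibble(newdata)[object$schema])
  if (nrow(x) == 0) return(factor(character(0), levels = object$classes))
  if (anyNA(x)) stop_validation("Prediction input contains missing values.")
  pred <- switch(object$config$kind,
    rf = {
      df <- data.frame(x, check.names = FALSE)
      # fixed seed: ranger resolves majority-vote ties randomly otherwise
      as.character(predict(object$fit, data = df, num.threads = 1,
                           seed = object$config$seed + 1L)$predictions)
    },
    dt = if (nrow(x) <= 16) {
      # direct tree traversal: the per-call model.frame machinery of the
      # formula interface is avoidable overhead on the real-time path
      flat <- attr(object$fit, "flat")
      vapply(seq_len(nrow(x)), function(r) dt_traverse(flat, x[r, ]),
             character(1))
    } else {
      df <- data.frame(x, check.names = FALSE)
      as.character(predict(object$fit, newdata = df, type = "class"))
    },
    knn = knn_predict(object$fit, x)
  )
  factor(pred, levels = object$classes)
}

# --- flattened decision-tree traversal --------------------------------------
# rpart stores nodes in binary-heap numbering (children of node k are 2k and
# 2k+1); each non-leaf's primary split is the first of its 1 + ncompete +
# nsurrogate rows in $splits.  ncat < 0 sends values below the cutpoint left,
# ncat > 0 sends them right.

dt_flatten <- function(fit) {
  fr <- fit$frame
  is_leaf <- fr$var == "<leaf>"
  nsplit <- ifelse(is_leaf, 0L, 1L + fr$ncompete + fr$nsurrogate)
  list(node_id = as.integer(rownames(fr)),
       is_leaf = is_leaf,
       var = as.character(fr$var),
       yval = fr$yval,
       srow = cumsum(c(0L, head(nsplit, -1))) + 1L,
       cut = fit$splits[, "index"],
       ncat = fit$splits[, "ncat"],
       classes = attr(fit, "ylevels"))
}

dt_traverse <- function(flat, x) {
  cur <- 1L
  repeat {
    row <- match(cur, flat$node_id)
    if (flat$is_leaf[row]) return(flat$classes[flat$yval[row]])
    s <- flat$srow[row]
    left <- if (flat$ncat[s] < 0) x[[flat$var[row]]] < flat$cut[s]
            else x[[flat$var[row]]] >= flat$cut[s]
    cur <- if (left) 2L * cur else 2L * cur + 1L
  }
}

# --- distance-weighted k-nearest neighbours ---------------------------------
# Standardise with training statistics; vote weight of a neighbour is the
# inverse of its Minkowski distance; a query coinciding with training points
# (distance ~ 0) is decided by those exact matches alone.

knn_fit <- function(x, y, k, p = 2) {
  mu <- colMeans(x)
  s <- apply(x, 2, sd)
  s[s < 1e-12] <- 1
  list(x = sweep(sweep(x, 2, mu), 2, s, "/"), y = y, k = k, p = p,
       center = mu, scale = s)
}

knn_predict <- function(fit, newx, chunk = 1024L) {
  newx <- sweep(sweep(newx, 2, fit$center), 2, fit$scale, "/")
  n <- nrow(newx)
  classes <- levels(fit$y)
  yi <- as.integer(fit$y)
  out <- character(n)
  tr_sq <- rowSums(fit$x^2)
  for (lo in seq(1, n, by = chunk)) {
    hi <- min(lo + chunk - 1L, n)
    q <- newx[lo:hi, , drop = FALSE]
    if (fit$p == 2) {
      # squared distances via the Gram expansion; selection and weighted
      # vote run in the compiled kernel
      cross <- -2 * tcrossprod(fit$x, q)
      win <- knn_vote(cross, rowSums(q^2), tr_sq, yi,
                      length(classes), fit$k)
      out[lo:hi] <- classes[win]
    } else {
      for (r in seq_len(nrow(q))) {
        d <- (colSums(abs(t(fit$x) - q[r, ])^fit$p))^(1 / fit$p)
        kth <- sort.int(d, partial = fit$k)[fit$k]
        ord <- which(d <= kth)
        ord <- ord[order(d[ord])][seq_len(min(fit$k, length(ord)))]
        dk <- d[ord]
        votes <- numeric(length(classes))
        if (any(dk <= 1e-8)) {
          for (i in ord[dk <= 1e-8]) votes[yi[i]] <- votes[yi[i]] + 1
        } else {
          w <- 1 / dk
          for (j in seq_along(ord)) votes[yi[ord[j]]] <- votes[yi[ord[j]]] + w[j]
        }
        out[lo + r - 1L] <- classes[which.max(votes)]
      }
    }
  }
  out
}

# --- grid search ------------------------------------------------------------

default_grid <- function(kind) {
  switch(kind,
    rf = list(num_trees = c(10, 25, 50), max_depth = c(10, 30)),
    dt = list(max_depth = c(2, 5, 19)),
    knn = list(k = c(5, 13, 21)),
    stop_config(paste0("Unknown model kind: ", kind)))
}

#' Exhaustive hyperparameter grid search
#'
#' Evaluates every combination in `grid` by stratified k-fold
#' cross-validation on `data` and returns the configuration with the highest
#' mean validation accuracy (ties resolved towards the earlier combination
#' in grid order: the first grid parameter varies fastest).
#'
#' @param data A labelled feature tibble.
#' @param kind `"rf"`, `"dt"` or `"knn"`.
#' @param grid Named list of candidate values; defaults to a small grid
#'   centred on the shipped optima.
#' @param folds Number of validation folds (default 5).
#' @param seed Seed controlling fold assignment and stochastic fits.
#' @param label Label column name.
#' @return The winning `model_config`, with the full results table attached
#'   as attribute `"results"`.
#' @export
grid_search <- function(data, kind = c("rf", "dt", "knn"), grid = NULL,
                        folds = 5, seed = 0L, label = "label") {
  kind <- match.arg(kind)
  grid <- grid %||% default_grid(kind)
  if (length(grid) == 0 || any(lengths(grid) == 0)) {
    stop_config("Grid must be a non-empty named list of candidate values.")
  }
  combos <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  y <- droplevels(as.factor(data[[label]]))
  fold_of <- stratified_folds(y, folds, seed)
  scores <- numeric(nrow(combos))
  for (i in seq_len(nrow(combos))) {
    cfg <- do.call(switch(kind, rf = rf_config, dt = dt_config,
                          knn = knn_config),
                   c(as.list(combos[i, , drop = FALSE]), list(seed = seed)))
    acc <- vapply(seq_len(folds), function(f) {
      tr <- data[fold_of != f, , drop = FALSE]
      va <- data[fold_of == f, , drop = FALSE]
      m <- fit_posture(tr, cfg, label = label)
      mean(as.character(predict(m, va)) == as.character(va[[label]]))
    }, numeric(1))
    scores[i] <- mean(acc)
  }
  best <- which.max(scores)  # ties -> first combination in grid order
  results <- tibble::as_tibble(combos)
  results$mean_accuracy <- scores
  out <- do.call(switch(kind, rf = rf_config, dt = dt_config, knn = knn_config),
                 c(as.list(combos[best, , drop = FALSE]), list(seed = seed)))
  attr(out, "results") <- results
  out
}

# --- persistence ------------------------------------------------------------

MODEL_FORMAT <- "posturekit-model-1"

#' Save / load a fitted posture model
#'
#' Models are stored in a self-describing container with a format-version
#' tag; loading a file with a different tag, or a file that is not a model
#' container, raises a clear error.
#'
#' @param model A `posture_model`.
#' @param path File path.
#' @return `save_posture_model()` returns `path` invisibly;
#'   `load_posture_model()` the restored model (load after save reproduces
#'   predictions exactly).
#' @export
save_posture_model <- function(model, path) {
  stopifnot(inherits(model, "posture_model"))
  saveRDS(list(format = MODEL_FORMAT, model = model), path)
  invisible(path)
}

#' @rdname save_posture_model
#' @export
load_posture_model <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e) {
    abort(paste0("Cannot read model file ", path, ": ", conditionMessage(e)),
          class = "posturekit_model_io_error")
  })
  if (!is.list(obj) || !identical(obj$format, MODEL_FORMAT)) {
    abort(sprintf("File %s is not a %s container.", path, MODEL_FORMAT),
          class = "posturekit_model_io_error")
  }
  obj$model
}

#' @export
glance.posture_model <- function(x, ...) {
  tibble::tibble(kind = x$config$kind, n_features = length(x$schema),
                 n_train = x$n_train, n_classes = length(x$classes),
                 seed = x$config$seed)
}
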