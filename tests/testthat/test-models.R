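test_that("model configurations default to the tuned hyperparameters", {
  rf <- rf_config()
  expect_equal(rf[c("num_trees", "max_depth", "criterion")],
               list(num_trees = 25L, max_depth = 30L, criterion = "gini"))
  dt <- dt_config()
  expect_equal(dt[c("max_depth", "criterion")],
               list(max_depth = 19L, criterion = "gini"))
  knn <- knn_config()
  expect_equal(knn[c("k", "p", "weights")],
               list(k = 13L, p = 2, weights = "distance"))
})

test_that("all models separate clean clusters and are seed-deterministic", {
  d <- cluster_data()
  for (cfg in list(rf_config(seed = 2), dt_config(seed = 2),
                   knn_config(seed = 2))) {
    m <- fit_posture(d, cfg)
    expect_equal(as.character(predict(m, d)), as.character(d$label))
    m2 <- fit_posture(d, cfg)
    expect_identical(predict(m2, d), predict(m, d))
  }
})

test_that("prediction aligns columns by name and enforces the schema", {
  d <- cluster_data()
  m <- fit_posture(d, dt_config())
  permuted <- d[, c("f2", "f1", "label")]
  expect_identical(predict(m, permuted), predict(m, d))
  expect_error(predict(m, d[, c("f1", "label")]),
               class = "posturekit_schema_error")
  empty <- d[0, ]
  expect_length(predict(m, empty), 0)
})

test_that("configuration errors are caught at fit time", {
  d <- cluster_data(n_per = 5)
  expect_error(fit_posture(d, knn_config(k = 100)),
               class = "posturekit_config_error")
  one_class <- d[d$label == "standing", ]
  expect_error(fit_posture(one_class, dt_config()),
               class = "posturekit_degenerate_labels_error")
  d_na <- d
  d_na$f1[1] <- NA
  expect_error(fit_posture(d_na, dt_config()),
               class = "posturekit_validation_error")
})

test_that("single-tree forest approximately reproduces the decision tree", {
  d <- cluster_data(n_per = 50, sd = 0.3)
  rf1 <- fit_posture(d, rf_config(num_trees = 1, max_depth = 30, seed = 5))
  dt <- fit_posture(d, dt_config(max_depth = 30, seed = 5))
  agreement <- mean(predict(rf1, d) == predict(dt, d))
  expect_gte(agreement, 0.9)
})

test_that("distance-weighted 1-NN memorises its training set", {
  d <- cluster_data(n_per = 20, sd = 1.5)  # heavily overlapping clusters
  m <- fit_posture(d, knn_config(k = 1))
  expect_equal(as.character(predict(m, d)), as.character(d$label))
})

test_that("distance-weighted KNN matches a brute-force reference", {
  set.seed(31)
  n <- 80
  d <- tibble::tibble(f1 = rnorm(n), f2 = rnorm(n), f3 = rnorm(n),
                      label = factor(sample(posture_levels(), n, TRUE),
                                     levels = posture_levels()))
  q <- tibble::tibble(f1 = rnorm(25), f2 = rnorm(25), f3 = rnorm(25))
  k <- 7
  m <- fit_posture(d, knn_config(k = k))
  got <- as.character(predict(m, q))
  # reference: explicit standardisation, full sort, inverse-distance votes
  x <- scale(as.matrix(d[1:3]))
  qx <- scale(as.matrix(q), center = attr(x, "scaled:center"),
              scale = attr(x, "scaled:scale"))
  for (i in seq_len(nrow(qx))) {
    dist <- sqrt(colSums((t(x) - qx[i, ])^2))
    nn <- order(dist)[1:k]
    votes <- tapply(1 / dist[nn], as.character(d$label[nn]), sum)
    expect_equal(got[i], names(votes)[which.max(votes)])
  }
})

test_that("models are equivariant under class relabelling", {
  d <- cluster_data(n_per = 40, sd = 0.3)
  perm <- c(standing = "lying", sitting = "bending",
            bending = "standing", lying = "sitting")
  d2 <- d
  d2$label <- factor(unname(perm[as.character(d$label)]),
                     levels = posture_levels())
  for (cfg in list(rf_config(seed = 3), dt_config(seed = 3),
                   knn_config(seed = 3))) {
    p1 <- as.character(predict(fit_posture(d, cfg), d))
    p2 <- as.character(predict(fit_posture(d2, cfg), d))
    expect_identical(unname(perm[p1]), p2)
  }
})

test_that("grid search selects the config the data demand", {
  single <- grid_search(cluster_data(), "dt", grid = list(max_depth = 7))
  expect_equal(single$max_depth, 7L)

  # XOR-like labels need depth > 1
  set.seed(17)
  n <- 200
  x1 <- rnorm(n) + rep(c(0, 4), n / 2)
  x2 <- rnorm(n) + rep(c(0, 4, 4, 0), n / 4)
  xorlab <- ifelse(rep(c(0, 4, 4, 0), n / 4) == rep(c(0, 4), n / 2),
                   "standing", "lying")
  d <- tibble::tibble(f1 = x1, f2 = x2,
                      label = factor(xorlab, levels = posture_levels()))
  best <- grid_search(d, "dt", grid = list(max_depth = c(1, 19)),
                      folds = 4, seed = 1)
  expect_equal(best$max_depth, 19L)
  expect_error(grid_search(d, "dt", grid = list()),
               class = "posturekit_config_error")
  best2 <- grid_search(d, "dt", grid = list(max_depth = c(1, 19)),
                       folds = 4, seed = 1)
  expect_identical(attr(best2, "results"), attr(best, "results"))
})

test_that("model persistence round-trips and rejects foreign files", {
  d <- cluster_data(n_per = 25)
  m <- fit_posture(d, rf_config(seed = 8))
  path <- withr::local_tempfile(fileext = ".rds")
  save_posture_model(m, path)
  back <- load_posture_model(path)
  expect_identical(predict(back, d), predict(m, d))

  other <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(format = "something-else"), other)
  expect_error(load_posture_model(other), class = "posturekit_model_io_error")
  corrupt <- withr::local_tempfile(fileext = ".rds")
  writeLines("not an rds", corrupt)
  expect_error(load_posture_model(corrupt),
               class = "posturekit_model_io_error")
})

test_that("the fast single-row tree path agrees with batch prediction", {
  co <- simulate_cohort(2, seed = 6,
                        schedule = posture_schedule(duration_s = 6, cycles = 1))
  feats <- cohort_features(co)
  m <- fit_posture(feats, dt_config())
  set.seed(12)
  idx <- sample(nrow(feats), 300)
  batch <- predict(m, feats[idx, ])
  single <- vapply(idx, function(r) as.character(predict(m, feats[r, ])),
                   character(1))
  expect_identical(as.character(batch), single)
})
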