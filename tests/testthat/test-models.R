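test_that("metrics match their definitional oracles", {
  set.seed(14)
  for (rep in 1:20) {
    y <- rnorm(25)
    y_hat <- y + rnorm(25, 0, 0.3)
    ybar <- mean(y)
    expect_equal(r_squared(y, y_hat),
                 1 - sum((y - y_hat)^2) / sum((y - ybar)^2),
                 tolerance = 1e-12)
    expect_equal(r_squared(y, y_hat, mode = "eq3"),
                 sum((y_hat - ybar)^2) / sum((y - ybar)^2),
                 tolerance = 1e-12)
    expect_equal(rmse(y, y_hat), sqrt(sum((y - y_hat)^2) / 25),
                 tolerance = 1e-12)
  }
  y <- c(1, 2, 3)
  expect_equal(r_squared(y, y), 1)
  expect_equal(r_squared(y, y, mode = "eq3"), 1)
  expect_equal(r_squared(y, rep(2, 3)), 0)
  expect_equal(rmse(y, y), 0)
  expect_equal(r_squared(c(1, 2, 3), c(1.1, 1.9, 3.2)), 0.97,
               tolerance = 0.005)
  expect_equal(rmse(c(1, 3), c(2, 5)), sqrt(2.5), tolerance = 1e-4)
  # homogeneity of RMSE
  expect_equal(rmse(3 * y, 3 * c(1.1, 1.9, 3.2)),
               3 * rmse(y, c(1.1, 1.9, 3.2)), tolerance = 1e-12)
  expect_error(r_squared(rep(1, 4), 1:4), "zero variance")
  expect_error(rmse(numeric(0), numeric(0)), "empty")
})

test_that("train/validation split partitions the ids as specified", {
  ids <- sprintf("S%03d", 1:100)
  parts <- split_train_validation(ids, split_spec(seed = 5))
  expect_length(parts$train, 60L)
  expect_length(parts$validation, 40L)
  expect_length(intersect(parts$train, parts$validation), 0L)
  expect_setequal(c(parts$train, parts$validation), ids)
  expect_identical(parts, split_train_validation(ids, split_spec(seed = 5)))
  expect_false(identical(parts$train,
                         split_train_validation(ids,
                                                split_spec(seed = 6))$train))
  expect_error(split_train_validation(ids[1:50], split_spec()), "sum")
})

test_that("SVR nails a noiseless linear target and is seed-deterministic", {
  set.seed(15)
  X <- matrix(rnorm(60 * 4), 60, 4)
  y <- drop(X %*% c(1, -1, 2, 0.5)) + 3
  fit <- fit_svr(X, y, seed = 1)
  expect_gte(r_squared(y, predict(fit, X)), 0.99)
  fit2 <- fit_svr(X, y, seed = 1)
  expect_identical(predict(fit, X), predict(fit2, X))
  expect_error(fit_svr(X, c(y[-1], NA)), "non-finite")
})

test_that("BPNN is seed-deterministic and beats the mean predictor", {
  set.seed(16)
  X <- matrix(rnorm(80 * 3), 80, 3)
  y <- drop(2.8 + 0.4 * tanh(X %*% c(1, -0.5, 0.8))) + rnorm(80, 0, 0.02)
  f1 <- suppressWarnings(fit_bpnn(X, y, seed = 4))
  f2 <- suppressWarnings(fit_bpnn(X, y, seed = 4))
  expect_identical(predict(f1, X), predict(f2, X))
  expect_gt(r_squared(y, predict(f1, X)), 0)
  expect_error(fit_bpnn(X, y, learning_rate = -1), "strictly positive")
})

test_that("fit_model dispatches and validation beats the mean-only baseline", {
  lib <- smooth_library(generate_dataset("NGS", 100, seed = 21))
  tab <- simulate_sensor_table(lib, bundled_sensor("sentinel2"))
  X <- band_matrix(tab)
  y <- tab$nitrogen_mg_per_g
  parts <- split_train_validation(tab$sample_id, split_spec(seed = 21))
  itr <- match(parts$train, tab$sample_id)
  iva <- match(parts$validation, tab$sample_id)
  for (mt in c("SVM", "BPNN")) {
    fit <- suppressWarnings(
      fit_model(X[itr, ], y[itr], model_config(mt, seed = 2)))
    val_r2 <- r_squared(y[iva], predict(fit, X[iva, ]))
    expect_gt(val_r2, 0) # better than predicting the training mean
  }
})

test_that("evaluate_all fills the paired 36-row design deterministically", {
  libs <- lapply(stages(), function(st) {
    smooth_library(generate_dataset(st, 30, seed = 31))
  })
  names(libs) <- stages()
  sensors <- c("landsat8", "sentinel2", "gf6")
  tables <- lapply(sensors, function(s) {
    lapply(libs, simulate_sensor_table, sensor = bundled_sensor(s))
  })
  names(tables) <- sensors
  spec <- split_spec(n_train = 18, n_validation = 12, seed = 3)
  rep1 <- suppressWarnings(evaluate_all(tables, spec, seed = 7))
  expect_equal(nrow(rep1), 36L)
  expect_equal(nrow(unique(rep1[, c("sensor", "model", "stage", "split")])),
               36L)
  expect_true(all(rep1$rmse >= 0))
  rep2 <- suppressWarnings(evaluate_all(tables, spec, seed = 7))
  expect_identical(rep1, rep2)
  preds <- attr(rep1, "predictions")
  # paired splits: same validation ids for every sensor/model at one stage
  vids <- unique(subset(preds, stage == "NGS" & split == "validation",
                        select = c(sensor, model)))
  first <- NULL
  for (k in seq_len(nrow(vids))) {
    cur <- preds$sample_id[preds$stage == "NGS" &
                             preds$split == "validation" &
                             preds$sensor == vids$sensor[k] &
                             preds$model == vids$model[k]]
    if (is.null(first)) first <- cur
    expect_identical(cur, first)
  }
  # misaligned ids across sensors abort
  broken <- tables
  broken$gf6$NGS$sample_id <- rev(broken$gf6$NGS$sample_id)
  expect_error(suppressWarnings(evaluate_all(broken, spec, seed = 7)),
               "misaligned")
})
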