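#' Train/validation split specification
#'
#' Defaults to the 60/40 random split of a 100-sample stage library.
#'
#' @param n_train training-set size.
#' @param n_validation validation-set size.
#' @param seed integer seed for the random partition.
#' @return object of class `split_spec`.
#' @export
split_spec <- function(n_train = 60L, n_validation = 40L, seed = 1L) {
  n_train <- assert_count(n_train, "n_train")
  n_validation <- assert_count(n_validation, "n_validation")
  structure(list(n_train = n_train, n_validation = n_validation, seed = seed),
            class = "split_spec")
}

#' Randomly partition sample ids into training and validation sets
#'
#' Uniform draw without replacement, seeded; the two parts are disjoint and
#' together exhaust the input ids.
#'
#' @param ids vector of sample ids.
#' @param spec a [split_spec()]; its sizes must sum to `length(ids)`.
#' @return list with `train` and `validation` id vectors.
#' @export
split_train_validation <- function(ids, spec = split_spec()) {
  stopifnot(inherits(spec, "split_spec"))
  if (spec$n_train + spec$n_validation != length(ids)) {
    stop("split sizes do not sum to the library size", call. = FALSE)
  }
  train_idx <- with_seed(derive_seed(spec$seed, 31L),
                         sort(sample(length(ids), spec$n_train)))
  list(train = ids[train_idx], validation = ids[-train_idx])
}

#' Model configuration for the nitrogen estimators
#'
#' @param model_type `"SVM"` or `"BPNN"`.
#' @param seed integer seed (fold assignment for SVM; initialisation and
#'   holdout for BPNN).
#' @param ... hyperparameter overrides passed to [fit_svr()] or [fit_bpnn()].
#' @return object of class `model_config`.
#' @export
model_config <- function(model_type = c("SVM", "BPNN"), seed = 1L, ...) {
  model_type <- match.arg(model_type)
  structure(list(model_type = model_type, seed = seed, args = list(...)),
            class = "model_config")
}

#' Fit one nitrogen estimator
#'
#' Dispatches to [fit_svr()] (epsilon-SVR, RBF kernel, cross-validated grid
#' search) or [fit_bpnn()] (single hidden layer, backpropagation, early
#' stopping). Both standardize predictors and response on the training
#' statistics internally, so validation data pass through the training
#' transform.
#'
#' @param X_train training predictors, samples x bands.
#' @param y_train training response, mg/g.
#' @param config a [model_config()].
#' @return a fitted `svr_model` or `bpnn_model` (both have `predict`
#'   methods).
#' @export
fit_model <- function(X_train, y_train, config = model_config()) {
  stopifnot(inherits(config, "model_config"))
  args <- c(list(X = X_train, y = y_train, seed = config$seed), config$args)
  if (config$model_type == "SVM") {
    do.call(fit_svr, args)
  } else {
    do.call(fit_bpnn, args)
  }
}

#' Evaluate SVM and BPNN estimators across sensors and stages
#'
#' Fills the full evaluation design: for every stage one shared seeded 60/40
#' split is drawn and reused across all sensors and model types (so sensor
#' and model comparisons are paired), each model is trained on all VNIR bands
#' of the sensor's simulated table, and training/validation R-squared and
#' RMSE are reported.
#'
#' @param tables nested list: `tables[[sensor]][[stage]]` is the
#'   `band_table` for that sensor and stage; all sensors must be derived from
#'   the same libraries (identical sample ids per stage).
#' @param spec a [split_spec()] (sizes applied per stage; sub-seeded by
#'   stage so stages get independent splits).
#' @param model_types model types to run.
#' @param seed master seed for model fitting.
#' @param r2_mode passed to [r_squared()].
#' @return data.frame with one row per sensor x model x stage x split:
#'   `sensor, model, stage, split, r2, rmse`, plus an attribute
#'   `predictions` (long data.frame of measured vs predicted values for
#'   scatter plots).
#' @export
evaluate_all <- function(tables, spec = split_spec(),
                         model_types = c("SVM", "BPNN"), seed = 1L,
                         r2_mode = "standard") {
  stopifnot(is.list(tables), length(tables) >= 1L)
  sensors <- names(tables)
  stage_names <- names(tables[[1]])
  rows <- list()
  preds <- list()
  for (stage in stage_names) {
    ids <- tables[[1]][[stage]]$sample_id
    for (s in sensors) {
      if (!identical(tables[[s]][[stage]]$sample_id, ids)) {
        stop("sample ids misaligned across sensors for stage ", stage,
             call. = FALSE)
      }
    }
    stage_spec <- split_spec(spec$n_train, spec$n_validation,
                             derive_seed(spec$seed, match(stage, stage_names)))
    parts <- split_train_validation(ids, stage_spec)
    for (s in sensors) {
      tab <- tables[[s]][[stage]]
      X <- band_matrix(tab)
      y <- tab$nitrogen_mg_per_g
      itr <- match(parts$train, ids)
      iva <- match(parts$validation, ids)
      for (mt in model_types) {
        fit <- fit_model(X[itr, , drop = FALSE], y[itr],
                         model_config(mt, seed = derive_seed(seed, 41L)))
        for (split in c("training", "validation")) {
          idx <- if (split == "training") itr else iva
          y_hat <- stats::predict(fit, X[idx, , drop = FALSE])
          rows[[length(rows) + 1L]] <- data.frame(
            sensor = s, model = mt, stage = stage, split = split,
            r2 = r_squared(y[idx], y_hat, mode = r2_mode),
            rmse = rmse(y[idx], y_hat), stringsAsFactors = FALSE)
          preds[[length(preds) + 1L]] <- data.frame(
            sensor = s, model = mt, stage = stage, split = split,
            sample_id = ids[idx], measured = y[idx], predicted = y_hat,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "predictions") <- do.call(rbind, preds)
  out
}
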