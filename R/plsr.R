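#' Fit a partial least squares regression by NIPALS
#'
#' From-scratch single-response NIPALS: predictors are autoscaled (centered,
#' unit sd) and the response centered; each component extracts the weight
#' vector proportional to the current X'y covariance, scores, loadings, then
#' deflates both blocks. Regression coefficients are back-transformed to the
#' original predictor scale, so [predict_plsr()] works on raw inputs.
#'
#' For a single response the NIPALS inner loop converges in one pass; the
#' iteration is retained defensively with tolerance 1e-10 and a 500-iteration
#' cap.
#'
#' @param X numeric matrix or data.frame, samples x predictors, no missing
#'   values, >= 3 rows.
#' @param y numeric response vector.
#' @param n_components number of latent components, in
#'   `[1, ncol(X)]`.
#' @return object of class `plsr_model` with elements `n_components`,
#'   `x_mean`, `x_sd`, `y_mean`, `weights`, `x_loadings`, `y_loadings`,
#'   `scores`, `coefficients` (original scale), `intercept`, `fitted`.
#' @export
fit_plsr <- function(X, y, n_components) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (anyNA(X) || anyNA(y)) stop("missing values not allowed", call. = FALSE)
  if (nrow(X) < 3L) stop("need at least 3 samples", call. = FALSE)
  if (nrow(X) != length(y)) stop("X rows and y length disagree", call. = FALSE)
  n_components <- assert_count(n_components, "n_components")
  if (n_components > ncol(X)) {
    stop("n_components exceeds the number of predictors", call. = FALSE)
  }
  x_mean <- colMeans(X)
  x_sd <- apply(X, 2L, stats::sd)
  zero_var <- x_sd == 0
  if (any(zero_var)) {
    nm <- colnames(X)[zero_var]
    if (is.null(nm)) nm <- paste0("predictor ", which(zero_var))
    stop("zero-variance predictor: ", nm[1], call. = FALSE)
  }
  y_mean <- mean(y)

  Xd <- sweep(sweep(X, 2L, x_mean), 2L, x_sd, `/`)
  yd <- y - y_mean

  p <- ncol(X)
  W <- matrix(0, p, n_components)
  P <- matrix(0, p, n_components)
  Q <- numeric(n_components)
  Tm <- matrix(0, nrow(X), n_components)

  nw1 <- NA_real_
  extracted <- 0L
  for (k in seq_len(n_components)) {
    w <- drop(crossprod(Xd, yd))
    nw <- sqrt(sum(w^2))
    if (k == 1L) {
      if (nw < 1e-300) {
        stop("no covariance between predictors and response", call. = FALSE)
      }
      nw1 <- nw
    } else if (nw < 1e-10 * nw1) {
      # deflation exhausted the covariance (e.g. collinear predictors):
      # keep the components found so far
      break
    }
    w <- w / nw
    for (iter in seq_len(500L)) {
      tt <- drop(Xd %*% w)
      q <- sum(yd * tt) / sum(tt^2)
      w_new <- drop(crossprod(Xd, yd)) # single-y: fixed point after one pass
      w_new <- w_new / sqrt(sum(w_new^2))
      if (sqrt(sum((w_new - w)^2)) < 1e-10) {
        w <- w_new
        break
      }
      w <- w_new
    }
    tt <- drop(Xd %*% w)
    tt2 <- sum(tt^2)
    pl <- drop(crossprod(Xd, tt)) / tt2
    q <- sum(yd * tt) / tt2
    Xd <- Xd - tcrossprod(tt, pl)
    yd <- yd - q * tt
    W[, k] <- w
    P[, k] <- pl
    Q[k] <- q
    Tm[, k] <- tt
    extracted <- k
  }
  if (extracted < n_components) {
    W <- W[, seq_len(extracted), drop = FALSE]
    P <- P[, seq_len(extracted), drop = FALSE]
    Q <- Q[seq_len(extracted)]
    Tm <- Tm[, seq_len(extracted), drop = FALSE]
    n_components <- extracted
  }

  # coefficients on the autoscaled X, then back to the original scale
  beta_scaled <- W %*% solve(crossprod(P, W), Q)
  coef_orig <- drop(beta_scaled) / x_sd
  intercept <- y_mean - sum(coef_orig * x_mean)

  model <- structure(
    list(n_components = n_components, x_mean = x_mean, x_sd = x_sd,
         y_mean = y_mean, weights = W, x_loadings = P, y_loadings = Q,
         scores = Tm, coefficients = coef_orig, intercept = intercept,
         band_names = colnames(X)),
    class = "plsr_model"
  )
  model$fitted <- predict_plsr(model, X)
  model
}

#' @export
print.plsr_model <- function(x, ...) {
  cat(sprintf("plsr_model: %d components, %d predictors\n",
              x$n_components, length(x$coefficients)))
  invisible(x)
}

#' Predict from a fitted PLSR model
#'
#' @param model a [fit_plsr()] model.
#' @param X new predictor matrix with the model's column count (and names,
#'   if the model was fitted with names).
#' @return predicted response vector.
#' @export
predict_plsr <- function(model, X) {
  stopifnot(inherits(model, "plsr_model"))
  X <- as.matrix(X)
  if (ncol(X) != length(model$coefficients)) {
    stop("predictor count does not match the model", call. = FALSE)
  }
  if (!is.null(model$band_names) && !is.null(colnames(X)) &&
      !identical(colnames(X), model$band_names)) {
    stop("predictor names do not match the model", call. = FALSE)
  }
  drop(X %*% model$coefficients) + model$intercept
}

# Prediction through the deflation recursion (scores recomputed from the
# stored weights/loadings); must agree with the coefficient path to 1e-10.
predict_plsr_recursive <- function(model, X) {
  X <- as.matrix(X)
  Xd <- sweep(sweep(X, 2L, model$x_mean), 2L, model$x_sd, `/`)
  yhat <- rep(model$y_mean, nrow(X))
  for (k in seq_len(model$n_components)) {
    tt <- drop(Xd %*% model$weights[, k])
    yhat <- yhat + model$y_loadings[k] * tt
    Xd <- Xd - tcrossprod(tt, model$x_loadings[, k])
  }
  yhat
}

#' Evaluate one band combination with PLSR
#'
#' Fits a PLSR on the named bands of a simulated band table and reports the
#' training-set R-squared (the single-R² convention of combination tables).
#'
#' @param table a `band_table`.
#' @param bands character vector of band names, subset of the table's bands.
#' @param y response vector; defaults to the table's nitrogen column.
#' @param n_components latent components; default `min(3, length(bands))`.
#' @param r2_mode passed to [r_squared()].
#' @return one-row data.frame `sensor, stage, band_combination,
#'   n_components, r2_train`.
#' @export
evaluate_combination <- function(table, bands, y = table$nitrogen_mg_per_g,
                                 n_components = min(3L, length(bands)),
                                 r2_mode = "standard") {
  stopifnot(inherits(table, "band_table"))
  unknown <- setdiff(bands, attr(table, "band_names"))
  if (length(unknown)) {
    stop("unknown band name: ", unknown[1], call. = FALSE)
  }
  X <- band_matrix(table)[, bands, drop = FALSE]
  fit <- fit_plsr(X, y, n_components)
  data.frame(sensor = attr(table, "sensor"),
             stage = unique(table$stage)[1],
             band_combination = paste(bands, collapse = ","),
             n_components = n_components,
             r2_train = r_squared(y, fit$fitted, mode = r2_mode),
             stringsAsFactors = FALSE)
}

#' Band-removal ablation of a PLSR combination
#'
#' Evaluates the base combination, then the combination with each removable
#' band deleted in turn, reporting the drop in training R-squared.
#'
#' @param table a `band_table`.
#' @param base_bands band names of the base combination.
#' @param removable bands to remove one at a time (subset of `base_bands`).
#' @param y response; defaults to the table's nitrogen column.
#' @param n_components components for every fit; default
#'   `min(3, length(base_bands))`, capped at the remaining band count per fit.
#' @param r2_mode passed to [r_squared()].
#' @return data.frame with one row for the base fit (`removed = ""`) and one
#'   per removal, with columns of [evaluate_combination()] plus `removed` and
#'   `delta_r2` (base minus ablated).
#' @export
ablation_table <- function(table, base_bands, removable = character(),
                           y = table$nitrogen_mg_per_g,
                           n_components = min(3L, length(base_bands)),
                           r2_mode = "standard") {
  if (!all(removable %in% base_bands)) {
    stop("`removable` must be a subset of `base_bands`", call. = FALSE)
  }
  base <- evaluate_combination(table, base_bands, y, n_components, r2_mode)
  base$removed <- ""
  base$delta_r2 <- 0
  rows <- lapply(removable, function(b) {
    keep <- setdiff(base_bands, b)
    rep_ <- evaluate_combination(table, keep, y,
                                 min(n_components, length(keep)), r2_mode)
    rep_$removed <- b
    rep_$delta_r2 <- base$r2_train - rep_$r2_train
    rep_
  })
  out <- do.call(rbind, c(list(base), rows))
  rownames(out) <- NULL
  out
}
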