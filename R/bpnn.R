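# Single-hidden-layer backpropagation network for small tabular regression.
# Logistic-sigmoid hidden units, linear output, full-batch gradient descent
# with momentum, early stopping on an internal holdout. Written in-package
# because no neural network library is available in the environment.

#' Fit a backpropagation neural network regressor
#'
#' One hidden layer of `hidden` logistic units (default `2 * ncol(X) + 1`)
#' and a linear output, trained by full-batch gradient descent with momentum
#' on standardized inputs and response. A seeded 20% internal holdout drives
#' early stopping: training keeps the weights with the best holdout error and
#' stops after `patience` epochs without improvement. Deterministic under
#' `seed` (weight initialisation, holdout assignment).
#'
#' @param X training predictors, samples x bands.
#' @param y training response, mg/g.
#' @param hidden hidden layer size (>= 1); default `2 * ncol(X) + 1`.
#' @param learning_rate gradient step size on standardized data.
#' @param max_epochs training epoch cap.
#' @param patience early-stopping patience in epochs.
#' @param holdout_frac fraction of the training set held out internally.
#' @param momentum momentum coefficient.
#' @param seed integer seed.
#' @return object of class `bpnn_model`.
#' @export
fit_bpnn <- function(X, y, hidden = NULL, learning_rate = 0.1,
                     max_epochs = 2000L, patience = 200L,
                     holdout_frac = 0.2, momentum = 0.9, seed = 1L) {
  X <- as.matrix(X)
  if (anyNA(X) || anyNA(y) || any(!is.finite(X)) || any(!is.finite(y))) {
    stop("non-finite values in the training data", call. = FALSE)
  }
  if (is.null(hidden)) hidden <- 2L * ncol(X) + 1L
  hidden <- assert_count(hidden, "hidden")
  if (learning_rate <= 0 || max_epochs < 1 || patience < 1) {
    stop("hyperparameters must be strictly positive", call. = FALSE)
  }
  n <- nrow(X)
  x_mean <- colMeans(X)
  x_sd <- apply(X, 2L, stats::sd)
  x_sd[x_sd == 0] <- 1
  y_mean <- mean(y)
  y_sd <- stats::sd(y)
  if (y_sd == 0) y_sd <- 1
  Xs <- sweep(sweep(X, 2L, x_mean), 2L, x_sd, `/`)
  ys <- (y - y_mean) / y_sd

  state <- with_seed(derive_seed(seed, 21L), {
    n_hold <- max(1L, round(holdout_frac * n))
    hold <- sample(n, n_hold)
    p <- ncol(X)
    list(hold = hold,
         W1 = matrix(stats::runif(p * hidden, -0.5, 0.5), p, hidden),
         b1 = stats::runif(hidden, -0.5, 0.5),
         W2 = matrix(stats::runif(hidden, -0.5, 0.5), hidden, 1),
         b2 = stats::runif(1, -0.5, 0.5))
  })
  hold <- state$hold
  tr <- setdiff(seq_len(n), hold)
  Xt <- Xs[tr, , drop = FALSE]; yt <- ys[tr]
  Xh <- Xs[hold, , drop = FALSE]; yh <- ys[hold]

  W1 <- state$W1; b1 <- state$b1; W2 <- state$W2; b2 <- state$b2
  vW1 <- W1 * 0; vb1 <- b1 * 0; vW2 <- W2 * 0; vb2 <- 0
  best <- list(W1 = W1, b1 = b1, W2 = W2, b2 = b2, err = Inf)
  stall <- 0L
  nt <- length(yt)
  converged <- FALSE

  forward <- function(Xin, W1, b1, W2, b2) {
    H <- stats::plogis(sweep(Xin %*% W1, 2L, b1, `+`))
    list(H = H, out = drop(H %*% W2) + b2)
  }

  for (epoch in seq_len(max_epochs)) {
    fw <- forward(Xt, W1, b1, W2, b2)
    err_out <- fw$out - yt                       # d(MSE/2)/d(out)
    gW2 <- crossprod(fw$H, err_out) / nt
    gb2 <- mean(err_out)
    dH <- (err_out %*% t(W2)) * fw$H * (1 - fw$H)
    gW1 <- crossprod(Xt, dH) / nt
    gb1 <- colMeans(dH)
    vW2 <- momentum * vW2 - learning_rate * gW2
    vb2 <- momentum * vb2 - learning_rate * gb2
    vW1 <- momentum * vW1 - learning_rate * gW1
    vb1 <- momentum * vb1 - learning_rate * gb1
    W2 <- W2 + vW2; b2 <- b2 + vb2; W1 <- W1 + vW1; b1 <- b1 + vb1

    hold_err <- mean((forward(Xh, W1, b1, W2, b2)$out - yh)^2)
    if (hold_err < best$err - 1e-10) {
      best <- list(W1 = W1, b1 = b1, W2 = W2, b2 = b2, err = hold_err)
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= patience) {
        converged <- TRUE
        break
      }
    }
  }
  if (!converged && max_epochs >= 50L) {
    warning("bpnn: holdout error still improving at max_epochs; ",
            "returning best weights so far", call. = FALSE)
  }

  structure(list(W1 = best$W1, b1 = best$b1, W2 = best$W2, b2 = best$b2,
                 hidden = hidden, x_mean = x_mean, x_sd = x_sd,
                 y_mean = y_mean, y_sd = y_sd, holdout_mse = best$err),
            class = "bpnn_model")
}

#' @export
predict.bpnn_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (ncol(X) != length(object$x_mean)) {
    stop("predictor count does not match the model", call. = FALSE)
  }
  Xs <- sweep(sweep(X, 2L, object$x_mean), 2L, object$x_sd, `/`)
  H <- stats::plogis(sweep(Xs %*% object$W1, 2L, object$b1, `+`))
  (drop(H %*% object$W2) + object$b2) * object$y_sd + object$y_mean
}
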