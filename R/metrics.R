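#' Coefficient of determination
#'
#' Default mode is the standard `1 - SSres/SStot`. The `"eq3"` mode computes
#' the explained-variance ratio `sum((yhat - ybar)^2) / sum((y - ybar)^2)`
#' instead, which equals the default for a least-squares linear fit on its
#' training data but can exceed 1 for biased nonlinear predictors; it is kept
#' available because some evaluation conventions print it.
#'
#' @param y measured values.
#' @param y_hat predicted values, same length (>= 2).
#' @param mode `"standard"` (default) or `"eq3"`.
#' @return R-squared, unitless.
#' @export
r_squared <- function(y, y_hat, mode = c("standard", "eq3")) {
  mode <- match.arg(mode)
  if (length(y) != length(y_hat)) stop("length mismatch", call. = FALSE)
  if (length(y) < 2L) stop("need at least 2 observations", call. = FALSE)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) {
    stop("undefined R-squared: zero variance in `y`", call. = FALSE)
  }
  if (mode == "standard") {
    1 - sum((y - y_hat)^2) / ss_tot
  } else {
    sum((y_hat - mean(y))^2) / ss_tot
  }
}

#' Root mean square error
#'
#' @param y measured values, mg/g.
#' @param y_hat predicted values, same length (>= 1).
#' @return RMSE in the units of `y`.
#' @export
rmse <- function(y, y_hat) {
  if (length(y) != length(y_hat)) stop("length mismatch", call. = FALSE)
  if (!length(y)) stop("empty vectors", call. = FALSE)
  sqrt(mean((y - y_hat)^2))
}
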