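test_that("full-component NIPALS reproduces OLS on full-rank problems", {
  set.seed(6)
  for (rep in 1:50) {
    n <- sample(8:15, 1)
    p <- sample(2:5, 1)
    X <- matrix(rnorm(n * p), n, p)
    y <- rnorm(n)
    fit <- fit_plsr(X, y, n_components = p)
    expect_equal(predict_plsr(fit, X), ols_oracle(X, y), tolerance = 1e-8)
  }
})

test_that("single predictor with one component equals simple regression", {
  set.seed(7)
  x <- matrix(rnorm(20), 20, 1)
  y <- 2 + 3 * x[, 1] + rnorm(20, 0, 0.5)
  fit <- fit_plsr(x, y, 1)
  lm_fit <- unname(cbind(1, x) %*% solve(crossprod(cbind(1, x)),
                                         crossprod(cbind(1, x), y)))
  expect_equal(predict_plsr(fit, x), drop(lm_fit), tolerance = 1e-10)
})

test_that("training R2 is non-decreasing in the component count", {
  set.seed(8)
  X <- matrix(rnorm(40 * 6), 40, 6)
  y <- X %*% rnorm(6) + rnorm(40)
  r2 <- vapply(1:6, function(k) {
    fit <- fit_plsr(X, y, k)
    r_squared(drop(y), fit$fitted)
  }, numeric(1))
  expect_true(all(diff(r2) >= -1e-10))
})

test_that("NIPALS invariants: score orthogonality and path equivalence", {
  set.seed(9)
  for (rep in 1:10) {
    n <- sample(6:10, 1)
    p <- sample(3:8, 1)
    X <- matrix(rnorm(n * p), n, p)
    y <- rnorm(n)
    k <- min(p, n - 2L, 4L)
    fit <- fit_plsr(X, y, k)
    G <- crossprod(fit$scores)
    off <- G - diag(diag(G))
    expect_lt(max(abs(off)) / max(diag(G)), 1e-8)
    # coefficient path equals the deflation recursion
    Xnew <- matrix(rnorm(5 * p), 5, p)
    expect_equal(predict_plsr(fit, Xnew),
                 canopysat:::predict_plsr_recursive(fit, Xnew),
                 tolerance = 1e-10)
  }
})

test_that("prediction centering and affine invariance hold", {
  set.seed(10)
  X <- matrix(rnorm(30 * 4), 30, 4)
  y <- X %*% c(1, -2, 0.5, 3) + rnorm(30, 0, 0.1)
  fit <- fit_plsr(X, y, 2)
  # mean row predicts the response mean
  expect_equal(predict_plsr(fit, matrix(colMeans(X), 1)), mean(y),
               tolerance = 1e-10)
  # fitted values are the training predictions
  expect_equal(fit$fitted, predict_plsr(fit, X), tolerance = 1e-12)
  # rescaling a predictor column and refitting leaves predictions unchanged
  X2 <- X
  X2[, 2] <- X2[, 2] * 37
  fit2 <- fit_plsr(X2, y, 2)
  expect_equal(predict_plsr(fit2, X2), predict_plsr(fit, X),
               tolerance = 1e-8)
  expect_error(fit_plsr(cbind(X, 0 * X[, 1]), y, 2), "zero-variance")
  expect_error(fit_plsr(X, y, 9), "exceeds")
  expect_error(predict_plsr(fit, X[, 1:2]), "predictor count")
})

test_that("combination evaluation reports training R2 with validation", {
  set.seed(11)
  X <- matrix(runif(200 * 5, 0.05, 0.9), 200, 5)
  colnames(X) <- paste0("B", 1:5)
  nit <- runif(200, 2, 3.9)
  tab <- toy_band_table(X, nit)
  # self-consistency: a full fit's fitted values are recovered exactly
  fit <- fit_plsr(X, nit, 5)
  tab_self <- toy_band_table(X, fit$fitted)
  expect_equal(evaluate_combination(tab_self, paste0("B", 1:5),
                                    n_components = 5)$r2_train,
               1, tolerance = 1e-9)
  # independent noise: R2 stays small
  expect_lt(evaluate_combination(tab, paste0("B", 1:5))$r2_train, 0.1)
  expect_error(evaluate_combination(tab, c("B1", "nope")), "unknown band")
})

test_that("ablation finds the planted signal band and ignores collinear ones", {
  set.seed(12)
  n <- 100
  signal <- runif(n, 0.2, 0.8)
  X <- cbind(S = signal,
             N1 = runif(n, 0.2, 0.8),
             N2 = runif(n, 0.2, 0.8),
             DUP = signal) # perfectly collinear with S
  nit <- 2 + 2 * signal + rnorm(n, 0, 0.05)
  tab <- toy_band_table(X, nit)
  # empty removable list degenerates to the base report
  base_only <- ablation_table(tab, colnames(X))
  expect_equal(nrow(base_only), 1L)
  expect_identical(base_only$removed, "")
  ab <- ablation_table(tab, colnames(X), removable = colnames(X))
  # removing one of a duplicated pair costs nothing
  expect_equal(ab$delta_r2[ab$removed == "DUP"], 0, tolerance = 1e-8)
  # removing both copies is impossible per single-band ablation, so the
  # noise bands must show the smallest drops among non-duplicates
  drops <- ab$delta_r2[ab$removed %in% c("N1", "N2")]
  expect_true(all(abs(drops) < 0.05))
  expect_error(ablation_table(tab, c("S", "N1"), removable = "DUP"),
               "subset")
})

test_that("ablation flags the planted band once collinearity is removed", {
  set.seed(13)
  n <- 100
  signal <- runif(n, 0.2, 0.8)
  X <- cbind(S = signal, N1 = runif(n), N2 = runif(n), N3 = runif(n))
  nit <- 2 + 2 * signal + rnorm(n, 0, 0.05)
  tab <- toy_band_table(X, nit)
  ab <- ablation_table(tab, colnames(X), removable = colnames(X))
  removals <- ab[ab$removed != "", ]
  expect_identical(removals$removed[which.max(removals$delta_r2)], "S")
})
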