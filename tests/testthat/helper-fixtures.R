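# Shared fixtures: everything is generated in code, no stored data.

# A tiny spectral library with hand-set spectra on the full grid.
tiny_library <- function(n = 3L, value = NULL) {
  wl <- wavelength_grid()
  refl <- vapply(seq_len(n), function(i) {
    if (is.null(value)) {
      pmin(pmax(0.2 + 0.1 * sin(wl / (100 + 10 * i)), 0), 1)
    } else {
      rep(value, length(wl))
    }
  }, numeric(length(wl)))
  ids <- sprintf("S%02d", seq_len(n))
  colnames(refl) <- ids
  spectral_library(wl, refl,
                   data.frame(sample_id = ids, stage = "NGS",
                              nitrogen_mg_per_g = seq(2.5, 3.5,
                                                      length.out = n)))
}

# A band table built directly from a matrix (bypasses convolution) for
# screening/PLSR oracle tests.
toy_band_table <- function(X, nitrogen, sensor = "toy", stage = "NGS") {
  stopifnot(nrow(X) == length(nitrogen))
  if (is.null(colnames(X))) colnames(X) <- paste0("B", seq_len(ncol(X)))
  df <- cbind(data.frame(sample_id = sprintf("S%03d", seq_len(nrow(X))),
                         stage = stage, nitrogen_mg_per_g = nitrogen),
              as.data.frame(X))
  structure(df, sensor = sensor, band_names = colnames(X),
            class = c("band_table", "data.frame"))
}

# Independent rejection-sampling oracle for the truncated normal.
rejection_truncnorm <- function(n, mean, sd, bounds, seed) {
  set.seed(seed)
  out <- numeric(0)
  while (length(out) < n) {
    draw <- rnorm(2L * n, mean, sd)
    out <- c(out, draw[draw >= bounds[1] & draw <= bounds[2]])
  }
  out[seq_len(n)]
}

# Definitional Pearson correlation, written independently of the package.
pearson_oracle <- function(x, y) {
  mx <- sum(x) / length(x)
  my <- sum(y) / length(y)
  num <- sum((x - mx) * (y - my))
  num / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Explicit trapezoidal rule on a unit-step grid.
trapz_oracle <- function(y) {
  s <- 0
  for (i in seq_len(length(y) - 1L)) s <- s + (y[i] + y[i + 1L]) / 2
  s
}

# OLS with intercept via the normal equations.
ols_oracle <- function(X, y) {
  Xi <- cbind(1, as.matrix(X))
  beta <- solve(crossprod(Xi), crossprod(Xi, y))
  drop(Xi %*% beta)
}
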