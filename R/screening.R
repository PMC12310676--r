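#' Normalized-difference index of two band reflectances
#'
#' `(r_i - r_j) / (r_i + r_j)`, the NDVI-style construction applied to an
#' arbitrary band pair. Bounded in [-1, 1] for non-negative inputs and
#' antisymmetric under argument swap. Pairs with a zero-sum denominator are
#' returned as `NA` (recorded as missing, excluded from correlations).
#'
#' @param r_i,r_j non-negative band reflectances (vectorized).
#' @return the index, same length as the inputs; `NA` where `r_i + r_j = 0`.
#' @export
nd_index <- function(r_i, r_j) {
  if (any(r_i < 0, na.rm = TRUE) || any(r_j < 0, na.rm = TRUE)) {
    stop("band reflectances must be non-negative", call. = FALSE)
  }
  denom <- r_i + r_j
  out <- (r_i - r_j) / denom
  out[denom == 0] <- NA_real_
  out
}

#' Pearson product-moment correlation
#'
#' The screening statistic: centered cross-product over the square root of
#' the product of the centered sums of squares.
#'
#' @param x,y numeric vectors of equal length >= 3, each with nonzero
#'   variance.
#' @return signed correlation in [-1, 1].
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 observations", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed", call. = FALSE)
  dx <- x - mean(x)
  dy <- y - mean(y)
  ssx <- sum(dx^2)
  ssy <- sum(dy^2)
  if (ssx == 0 || ssy == 0) {
    stop("undefined correlation: zero variance input", call. = FALSE)
  }
  r <- sum(dx * dy) / sqrt(ssx * ssy)
  min(max(r, -1), 1)
}

#' Screen all band pairs by normalized-difference correlation with nitrogen
#'
#' For every unordered band pair (earlier band in sensor order first),
#' computes the per-sample normalized-difference index and its Pearson
#' correlation with nitrogen. Samples whose index is undefined (zero-sum
#' denominator) are excluded pairwise. The best pair maximizes `|r|`; ties
#' break on first pair in band order.
#'
#' @param table a `band_table` from [simulate_sensor_table()].
#' @param nitrogen nitrogen vector aligned with the table rows; defaults to
#'   the table's own `nitrogen_mg_per_g` column.
#' @return a `screen_result`: list with `sensor`, `stage`, `entries`
#'   (data.frame `band_i`, `band_j`, `r`, `abs_r`, `n_samples`) and `best`
#'   (one-row data.frame).
#' @export
screen_band_pairs <- function(table, nitrogen = table$nitrogen_mg_per_g) {
  stopifnot(inherits(table, "band_table"))
  bn <- attr(table, "band_names")
  if (length(nitrogen) != nrow(table)) {
    stop("nitrogen vector does not align with the band table", call. = FALSE)
  }
  if (length(bn) < 2L) stop("need at least two bands to screen", call. = FALSE)
  X <- band_matrix(table)
  pairs <- utils::combn(seq_along(bn), 2L)
  n_dropped <- 0L
  rows <- apply(pairs, 2L, function(p) {
    idx <- nd_index(X[, p[1]], X[, p[2]])
    ok <- !is.na(idx)
    n_dropped <<- n_dropped + sum(!ok)
    if (sum(ok) < 3L) {
      return(data.frame(band_i = bn[p[1]], band_j = bn[p[2]],
                        r = NA_real_, abs_r = NA_real_,
                        n_samples = sum(ok)))
    }
    r <- pearson_r(idx[ok], nitrogen[ok])
    data.frame(band_i = bn[p[1]], band_j = bn[p[2]], r = r, abs_r = abs(r),
               n_samples = sum(ok))
  })
  entries <- do.call(rbind, rows)
  if (all(is.na(entries$r))) {
    stop("screening failed: all band pairs undefined", call. = FALSE)
  }
  if (n_dropped > 0L) {
    message(sprintf("screen_band_pairs: %d undefined index values excluded",
                    n_dropped))
  }
  best <- entries[which.max(entries$abs_r), , drop = FALSE]
  rownames(best) <- NULL
  structure(list(sensor = attr(table, "sensor"),
                 stage = unique(table$stage)[1],
                 entries = entries, best = best),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf("screen_result: %s, stage %s, %d band pairs\n",
              x$sensor, x$stage, nrow(x$entries)))
  cat(sprintf("best |r|: %s vs %s, r = %.3f (n = %d)\n",
              x$best$band_i, x$best$band_j, x$best$r, x$best$n_samples))
  invisible(x)
}

#' Export / import a screening result as long-format CSV
#'
#' Rows `band_i, band_j, r, abs_r, n_samples`; lossless round-trip.
#'
#' @param result a `screen_result`.
#' @param path CSV path.
#' @param sort_by_abs_r write rows sorted by `abs_r` descending.
#' @return the exported data.frame, invisibly (writer); a data.frame
#'   (reader).
#' @export
screening_matrix_export <- function(result, path, sort_by_abs_r = FALSE) {
  stopifnot(inherits(result, "screen_result"))
  df <- result$entries
  if (sort_by_abs_r) df <- df[order(-df$abs_r), , drop = FALSE]
  readr::write_csv(df, path)
  invisible(df)
}

#' @rdname screening_matrix_export
#' @export
screening_matrix_import <- function(path) {
  as.data.frame(readr::read_csv(path, show_col_types = FALSE))
}
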