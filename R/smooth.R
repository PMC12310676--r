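#' Savitzky-Golay smoothing of a spectrum
#'
#' Local least-squares polynomial smoothing, the standard de-noising step for
#' field spectroradiometer canopy spectra. Interior points use the symmetric
#' convolution kernel; points within half a window of either end are fitted
#' with the same polynomial order on the asymmetric window that fits, so
#' polynomials of degree <= `polyorder` pass through unchanged everywhere.
#' Output is clipped to [0, 1] to preserve the reflectance invariant.
#'
#' @param spectrum list with `wavelength` and `reflectance` (class `spectrum`),
#'   or any list exposing those fields on a uniform grid.
#' @param window odd window length in points (>= 3). Default 15.
#' @param polyorder polynomial order, < window. Default 3.
#' @return the smoothed spectrum, same class and grid.
#' @export
smooth_spectrum <- function(spectrum, window = 15L, polyorder = 3L) {
  window <- assert_count(window, "window")
  if (window %% 2L == 0L || window < 3L) {
    stop("`window` must be an odd integer >= 3", call. = FALSE)
  }
  if (polyorder < 0 || polyorder >= window) {
    stop("`polyorder` must be non-negative and smaller than `window`",
         call. = FALSE)
  }
  y <- spectrum$reflectance
  if (window > length(y)) {
    stop("`window` exceeds the spectrum length", call. = FALSE)
  }
  out <- savgol_filter(y, window, polyorder)
  spectrum$reflectance <- pmin(pmax(out, 0), 1)
  spectrum
}

# Savitzky-Golay on a uniform grid with polynomial-fit edge handling.
savgol_filter <- function(y, window, polyorder) {
  n <- length(y)
  half <- (window - 1L) %/% 2L
  # symmetric kernel: first row of (X'X)^-1 X' for centred abscissa
  x <- (-half):half
  X <- outer(x, 0:polyorder, `^`)
  kernel <- (solve(crossprod(X)) %*% t(X))[1L, ]
  out <- stats::filter(y, rev(kernel), sides = 2)
  out <- as.numeric(out)
  # edges: least-squares polynomial on the leading/trailing window,
  # evaluated at the edge abscissae
  edge_fit <- function(idx, eval_at) {
    xe <- seq_along(idx) - 1
    Xe <- outer(xe, 0:polyorder, `^`)
    beta <- solve(crossprod(Xe), crossprod(Xe, y[idx]))
    drop(outer(eval_at, 0:polyorder, `^`) %*% beta)
  }
  out[seq_len(half)] <- edge_fit(seq_len(window), 0:(half - 1L))
  out[(n - half + 1L):n] <- edge_fit((n - window + 1L):n,
                                     (window - half):(window - 1L))
  out
}

#' Smooth every spectrum in a library
#'
#' @param library a `spectral_library`.
#' @inheritParams smooth_spectrum
#' @return the library with smoothed reflectance columns.
#' @export
smooth_library <- function(library, window = 15L, polyorder = 3L) {
  stopifnot(inherits(library, "spectral_library"))
  sm <- apply(library$reflectance, 2L, function(col) {
    smooth_spectrum(list(wavelength = library$wavelength, reflectance = col),
                    window, polyorder)$reflectance
  })
  colnames(sm) <- colnames(library$reflectance)
  library$reflectance <- sm
  library
}
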