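#' @keywords internal
"_PACKAGE"

#' Derive a reproducible sub-seed from a master seed
#'
#' All random streams in the package descend from one user-supplied integer
#' seed. Each logical stream (nitrogen draws, chlorophyll noise, spectrum
#' noise, splits, model initialisation, ...) gets its own sub-seed via a
#' fixed affine map modulo 2^31 - 1, so that changing one stream's draws
#' never perturbs another's.
#'
#' @param seed master seed, a single finite integer-valued number.
#' @param stream non-negative integer identifying the stream.
#' @return an integer in [1, 2^31 - 2] usable with [set.seed()].
#' @export
derive_seed <- function(seed, stream = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  stopifnot(is.numeric(stream), length(stream) == 1L, stream >= 0)
  m <- 2147483647 # 2^31 - 1, prime
  s <- (abs(as.numeric(seed)) %% m) * 48271 + as.numeric(stream) * 16807 + 1
  as.integer(s %% m + 1)
}

# Run `expr` under a given seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Scalar validation helpers -------------------------------------------------

assert_scalar <- function(x, name, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || (finite && !is.finite(x))) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  invisible(x)
}

assert_count <- function(x, name) {
  assert_scalar(x, name)
  if (x < 1 || x != as.integer(x)) {
    stop(sprintf("`%s` must be a positive integer", name), call. = FALSE)
  }
  invisible(as.integer(x))
}

#' The common 1-nm wavelength grid
#'
#' Canopy hyperspectra are handled on the full-range ASD grid:
#' 350 to 2500 nm in 1-nm steps, 2151 points.
#'
#' @return integer vector of wavelengths in nm.
#' @export
wavelength_grid <- function() 350:2500
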