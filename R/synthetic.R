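#' Draw canopy nitrogen values for one phenological stage
#'
#' Nitrogen concentrations are drawn from a truncated normal distribution on
#' the stage's bounds. The location parameter is calibrated so that the
#' truncated distribution's mean equals the stage target mean exactly, so
#' sample means converge on the target as n grows.
#'
#' @param stage one of `"NGS"`, `"NSS"`, `"ASS"`.
#' @param n number of samples to draw.
#' @param seed integer seed; identical seeds give identical draws.
#' @param params optional [stage_params()] override.
#' @return numeric vector of nitrogen concentrations, mg/g.
#' @export
sample_nitrogen <- function(stage, n, seed, params = stage_params(stage)) {
  n <- assert_count(n, "n")
  stopifnot(inherits(params, "stage_params"))
  mu <- truncnorm_location(params$n_mean, params$n_sd, params$n_bounds)
  with_seed(derive_seed(seed, 1L), {
    truncnorm::rtruncnorm(n, a = params$n_bounds[1], b = params$n_bounds[2],
                          mean = mu, sd = params$n_sd)
  })
}

#' Map nitrogen concentration to a chlorophyll index
#'
#' Nitrogen is a building block of chlorophyll a and b; the generator couples
#' the two through a linear link with additive gaussian noise, floored at
#' zero. At `noise_sd = 0` the map is strictly increasing in nitrogen
#' (provided `slope > 0` and the floor is not hit).
#'
#' @param n_value nitrogen concentration(s), mg/g.
#' @param slope positive link slope (chlorophyll-index units per mg/g).
#' @param intercept link intercept.
#' @param noise_sd gaussian noise sd on the chlorophyll scale.
#' @param seed integer seed for the noise draw.
#' @return non-negative chlorophyll index, same length as `n_value`.
#' @export
nitrogen_to_chlorophyll <- function(n_value, slope = 16, intercept = -14,
                                    noise_sd = 1.5, seed = 1L) {
  if (!is.numeric(n_value) || any(!is.finite(n_value))) {
    stop("`n_value` must be finite numeric", call. = FALSE)
  }
  assert_scalar(slope, "slope")
  if (slope <= 0) stop("`slope` must be > 0", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  eps <- if (noise_sd > 0) {
    with_seed(derive_seed(seed, 2L), stats::rnorm(length(n_value), 0, noise_sd))
  } else {
    0
  }
  pmax(0, slope * n_value + intercept + eps)
}

# Unit-height gaussian in wavelength.
gauss_bump <- function(lambda, center, sd) exp(-(lambda - center)^2 / (2 * sd^2))

#' Generate one synthetic canopy reflectance spectrum
#'
#' Parametric canopy spectrum on the 1-nm 350--2500 nm grid. The construction
#' is: a smooth visible continuum with a green peak; two gaussian chlorophyll
#' absorption wells (centres 450 and 670 nm) whose fractional depth increases
#' saturatingly with the chlorophyll index; a logistic red-edge rise whose
#' inflection wavelength shifts longward with chlorophyll; a NIR plateau set
#' by the stage amplitude times a per-sample lognormal structure factor; a
#' smooth SWIR decline with fixed water-absorption wells near 1450 and
#' 1940 nm; additive gaussian noise, then clipping to [0, 1].
#'
#' A per-sample lognormal "pigment jitter" multiplies the well depth,
#' injecting visible-region variance unrelated to nitrogen; the red-edge
#' inflection depends on chlorophyll only, so normalized differences of two
#' red-edge bands carry the cleanest nitrogen signal (the planted ground
#' truth the screening stage is expected to recover).
#'
#' @param chl non-negative chlorophyll index.
#' @param params a [stage_params()] object.
#' @param seed integer seed (structure factor, pigment jitter, noise).
#' @param well_depths maximum fractional absorption depths of the blue and
#'   red chlorophyll wells.
#' @return list with `wavelength` (nm) and `reflectance` (unitless), both of
#'   length 2151; class `spectrum`.
#' @export
generate_spectrum <- function(chl, params, seed,
                              well_depths = c(blue = 0.62, red = 0.80)) {
  assert_scalar(chl, "chl")
  if (chl < 0) stop("`chl` must be >= 0", call. = FALSE)
  stopifnot(inherits(params, "stage_params"))
  lambda <- wavelength_grid()

  draws <- with_seed(derive_seed(seed, 3L), {
    list(
      structure = stats::rlnorm(1, -params$structure_sdlog^2 / 2,
                                params$structure_sdlog),
      pigment = stats::rlnorm(1, -params$pigment_jitter_sdlog^2 / 2,
                              params$pigment_jitter_sdlog),
      noise = if (params$noise_sd > 0) {
        stats::rnorm(length(lambda), 0, params$noise_sd)
      } else {
        numeric(length(lambda))
      }
    )
  })

  # visible continuum with a green peak near 550 nm
  vis <- 0.115 + 0.025 * gauss_bump(lambda, 550, 45)
  # saturating chlorophyll absorption, fractional well depths
  depth <- draws$pigment * chl / (chl + 3)
  wells <- well_depths[["blue"]] * gauss_bump(lambda, 450, 30) +
    well_depths[["red"]] * gauss_bump(lambda, 670, 28)
  r_vis <- vis * (1 - pmin(depth * wells, 1))

  # NIR plateau and SWIR branch with water absorption wells
  plateau <- params$amplitude * draws$structure
  swir_shape <- (1 - 0.32 * stats::plogis((lambda - 1350) / 120)) *
    (1 - 0.50 * gauss_bump(lambda, 1450, 45)) *
    (1 - 0.72 * gauss_bump(lambda, 1940, 60))
  r_nir <- plateau * swir_shape

  # logistic red edge; inflection shifts longward with chlorophyll
  infl <- 690 + 45 * chl / (chl + 50)
  s <- stats::plogis((lambda - infl) / 10)
  refl <- r_vis * (1 - s) + r_nir * s + draws$noise

  structure(list(wavelength = lambda,
                 reflectance = pmin(pmax(refl, 0), 1)),
            class = "spectrum")
}

#' Generate a seeded synthetic canopy spectral library
#'
#' Couples [sample_nitrogen()], [nitrogen_to_chlorophyll()] and
#' [generate_spectrum()] into a library of `n` samples for one stage. All
#' randomness derives from the single `seed` through documented sub-seeds,
#' so identical calls yield bit-identical libraries.
#'
#' @inheritParams sample_nitrogen
#' @param chl_link list with the chlorophyll-link parameters `slope`,
#'   `intercept`, `noise_sd` passed to [nitrogen_to_chlorophyll()].
#' @return a `spectral_library`: list with `wavelength` (2151 nm grid),
#'   `reflectance` (2151 x n matrix, one column per sample) and `metadata`
#'   (data.frame `sample_id`, `stage`, `nitrogen_mg_per_g`).
#' @export
generate_dataset <- function(stage, n, seed, params = stage_params(stage),
                             chl_link = list(slope = 16, intercept = -14,
                                             noise_sd = 1.5)) {
  stage <- match_stage(stage)
  n <- assert_count(n, "n")
  nitrogen <- sample_nitrogen(stage, n, seed, params)
  chl <- nitrogen_to_chlorophyll(nitrogen, slope = chl_link$slope,
                                 intercept = chl_link$intercept,
                                 noise_sd = chl_link$noise_sd, seed = seed)
  refl <- vapply(seq_len(n), function(i) {
    generate_spectrum(chl[i], params, seed = derive_seed(seed, 100L + i))$reflectance
  }, numeric(length(wavelength_grid())))
  ids <- sprintf("%s_%03d", stage, seq_len(n))
  colnames(refl) <- ids
  spectral_library(wavelength = wavelength_grid(), reflectance = refl,
                   metadata = data.frame(sample_id = ids, stage = stage,
                                         nitrogen_mg_per_g = nitrogen,
                                         stringsAsFactors = FALSE))
}

#' Construct a spectral library container
#'
#' @param wavelength common wavelength grid, nm, strictly increasing with a
#'   uniform 1-nm step.
#' @param reflectance numeric matrix, wavelengths x samples, values in [0, 1].
#' @param metadata data.frame with columns `sample_id`, `stage`,
#'   `nitrogen_mg_per_g`; one row per reflectance column, ids unique.
#' @return object of class `spectral_library`.
#' @export
spectral_library <- function(wavelength, reflectance, metadata) {
  reflectance <- as.matrix(reflectance)
  if (length(wavelength) != nrow(reflectance)) {
    stop("wavelength grid and reflectance rows disagree", call. = FALSE)
  }
  steps <- diff(wavelength)
  if (length(steps) && (any(steps <= 0) || any(abs(steps - steps[1]) > 1e-9))) {
    stop("wavelength grid must be strictly increasing with a uniform step",
         call. = FALSE)
  }
  required <- c("sample_id", "stage", "nitrogen_mg_per_g")
  if (!all(required %in% names(metadata))) {
    stop("metadata must have columns ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(metadata) != ncol(reflectance)) {
    stop("metadata rows and reflectance columns disagree", call. = FALSE)
  }
  if (anyDuplicated(metadata$sample_id)) {
    stop("duplicate sample_id: ",
         metadata$sample_id[duplicated(metadata$sample_id)][1], call. = FALSE)
  }
  if (!is.null(colnames(reflectance)) &&
      !identical(colnames(reflectance), metadata$sample_id)) {
    stop("reflectance column names and metadata sample_id disagree",
         call. = FALSE)
  }
  colnames(reflectance) <- metadata$sample_id
  structure(list(wavelength = as.numeric(wavelength),
                 reflectance = reflectance,
                 metadata = metadata),
            class = "spectral_library")
}

#' @export
print.spectral_library <- function(x, ...) {
  cat(sprintf("spectral_library: %d samples x %d wavelengths (%g-%g nm)\n",
              ncol(x$reflectance), length(x$wavelength),
              min(x$wavelength), max(x$wavelength)))
  cat("stages:", paste(unique(x$metadata$stage), collapse = ", "), "\n")
  invisible(x)
}

#' Number of samples in a spectral library
#' @param library a `spectral_library`.
#' @return integer count.
#' @export
n_samples <- function(library) ncol(library$reflectance)
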