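#' Phenological stages
#'
#' The three apple phenological stages sampled in the study design this
#' package emulates: new-shoot-growing (NGS), new-shoot-stop-growing (NSS)
#' and autumn-shoot (ASS).
#'
#' @return character vector of stage codes.
#' @export
stages <- function() c("NGS", "NSS", "ASS")

match_stage <- function(stage) {
  if (!is.character(stage) || length(stage) != 1L || !(stage %in% stages())) {
    stop("unknown stage: must be one of ", paste(stages(), collapse = ", "),
         call. = FALSE)
  }
  stage
}

# Printed stage means of canopy nitrogen (mg/g) that the generator targets.
STAGE_N_MEAN <- c(NGS = 3.04, NSS = 2.82, ASS = 2.60)

# NIR plateau amplitude defaults: canopy reflectance highest at NGS,
# intermediate at NSS, lowest at ASS.
STAGE_AMPLITUDE <- c(NGS = 0.52, NSS = 0.46, ASS = 0.40)

#' Per-stage generator parameters
#'
#' Builds the parameter set controlling the synthetic canopy generator for
#' one phenological stage. Nitrogen is drawn from a truncated normal whose
#' *distribution mean* equals the stage target mean (the location parameter
#' is solved for, so truncation does not bias the mean); the NIR plateau
#' amplitude encodes the observed stage ordering of canopy brightness
#' (NGS > NSS > ASS).
#'
#' @param stage one of `"NGS"`, `"NSS"`, `"ASS"`.
#' @param n_mean target mean nitrogen concentration, mg/g.
#' @param n_sd nitrogen standard deviation before truncation, mg/g.
#' @param n_bounds truncation bounds `(low, high)`, mg/g.
#' @param amplitude NIR plateau reflectance scale (unitless, in (0, 1)).
#' @param noise_sd additive spectral noise standard deviation
#'   (reflectance units).
#' @param structure_sdlog lognormal sd of the per-sample canopy structure
#'   factor multiplying the NIR plateau.
#' @param pigment_jitter_sdlog lognormal sd of the per-sample pigment
#'   absorption-depth factor (visible-region variance unrelated to nitrogen).
#' @return an object of class `stage_params`.
#' @export
stage_params <- function(stage,
                         n_mean = STAGE_N_MEAN[[match_stage(stage)]],
                         n_sd = 0.30,
                         n_bounds = c(2.0, 3.9),
                         amplitude = STAGE_AMPLITUDE[[match_stage(stage)]],
                         noise_sd = 0.004,
                         structure_sdlog = 0.04,
                         pigment_jitter_sdlog = 0.06) {
  stage <- match_stage(stage)
  assert_scalar(n_mean, "n_mean"); assert_scalar(n_sd, "n_sd")
  stopifnot(length(n_bounds) == 2L, n_bounds[1] < n_bounds[2])
  if (!(n_bounds[1] < n_mean && n_mean < n_bounds[2])) {
    stop("n_mean must lie strictly inside n_bounds", call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (amplitude <= 0 || amplitude >= 1) {
    stop("amplitude must be in (0, 1)", call. = FALSE)
  }
  structure(
    list(stage = stage, n_mean = n_mean, n_sd = n_sd,
         n_bounds = as.numeric(n_bounds), amplitude = amplitude,
         noise_sd = noise_sd, structure_sdlog = structure_sdlog,
         pigment_jitter_sdlog = pigment_jitter_sdlog),
    class = "stage_params"
  )
}

#' @export
print.stage_params <- function(x, ...) {
  cat(sprintf(
    "Stage %s: N ~ truncNorm(mean %.2f, sd %.2f) on [%.1f, %.1f] mg/g; NIR amplitude %.2f; noise sd %.3g\n",
    x$stage, x$n_mean, x$n_sd, x$n_bounds[1], x$n_bounds[2], x$amplitude,
    x$noise_sd))
  invisible(x)
}

# Location parameter of the truncated normal whose mean equals `target`
# for given sd and bounds. Solved once per call; monotone in mu.
truncnorm_location <- function(target, sd, bounds) {
  f <- function(mu) {
    truncnorm::etruncnorm(a = bounds[1], b = bounds[2], mean = mu, sd = sd) -
      target
  }
  stats::uniroot(f, interval = c(bounds[1] - 4 * sd, bounds[2] + 4 * sd),
                 tol = 1e-10)$root
}
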