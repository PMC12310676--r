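#' Define one sensor band
#'
#' A band is either a `boxcar` (flat response between `lower` and `upper`)
#' or a `gaussian` (peak-normalized response with given `center` and `fwhm`).
#' Boxcars suit sensors published as wavelength ranges (Landsat-8, GF-6);
#' gaussians suit sensors published as centre wavelengths (Sentinel-2).
#'
#' @param name band name, e.g. `"red"`, `"RE1"`, `"NIR"`.
#' @param shape `"boxcar"` or `"gaussian"`.
#' @param lower,upper boxcar wavelength range, nm.
#' @param center,fwhm gaussian centre and full width at half maximum, nm.
#' @return object of class `band_def`.
#' @export
band_definition <- function(name, shape = c("boxcar", "gaussian"),
                            lower = NULL, upper = NULL,
                            center = NULL, fwhm = NULL) {
  shape <- match.arg(shape)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (shape == "boxcar") {
    assert_scalar(lower, "lower"); assert_scalar(upper, "upper")
    if (lower >= upper) stop("boxcar band needs lower < upper", call. = FALSE)
    if (lower < 350 || upper > 2500) {
      stop("band wavelengths must lie within 350-2500 nm", call. = FALSE)
    }
    band <- list(name = name, shape = shape, lower = lower, upper = upper)
  } else {
    assert_scalar(center, "center"); assert_scalar(fwhm, "fwhm")
    if (fwhm <= 0) stop("gaussian band needs fwhm > 0", call. = FALSE)
    if (center < 350 || center > 2500) {
      stop("band wavelengths must lie within 350-2500 nm", call. = FALSE)
    }
    band <- list(name = name, shape = shape, center = center, fwhm = fwhm)
  }
  structure(band, class = "band_def")
}

#' Define a sensor as an ordered band set
#'
#' @param name sensor name.
#' @param bands list of [band_definition()] objects with unique names.
#' @return object of class `sensor_def`.
#' @export
sensor_definition <- function(name, bands) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!length(bands) || !all(vapply(bands, inherits, logical(1), "band_def"))) {
    stop("`bands` must be a non-empty list of band_def objects", call. = FALSE)
  }
  nm <- vapply(bands, `[[`, character(1), "name")
  if (anyDuplicated(nm)) {
    stop("duplicate band name within sensor: ", nm[duplicated(nm)][1],
         call. = FALSE)
  }
  structure(list(name = name, bands = bands), class = "sensor_def")
}

#' @export
print.sensor_def <- function(x, ...) {
  cat(sprintf("sensor %s: %d bands (%s)\n", x$name, length(x$bands),
              paste(band_names(x), collapse = ", ")))
  invisible(x)
}

#' Band names of a sensor, in order
#' @param sensor a `sensor_def`.
#' @return character vector.
#' @export
band_names <- function(sensor) {
  vapply(sensor$bands, `[[`, character(1), "name")
}

#' Read a sensor definition from a JSON config
#'
#' Schema: `{"name": ..., "bands": [{"name", "shape", "lower"?, "upper"?,
#' "center"?, "fwhm"?}, ...]}`.
#'
#' @param path path to the JSON file.
#' @return a `sensor_def`.
#' @export
read_sensor_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(cfg$name) || is.null(cfg$bands)) {
    stop("sensor config needs `name` and `bands`: ", path, call. = FALSE)
  }
  bands <- lapply(cfg$bands, function(b) {
    band_definition(name = b$name, shape = b$shape,
                    lower = b$lower, upper = b$upper,
                    center = b$center, fwhm = b$fwhm)
  })
  sensor_definition(cfg$name, bands)
}

#' Bundled sensor definitions
#'
#' Returns one of the three bundled sensor configs: `landsat8` and `gf6` as
#' published wavelength ranges (boxcar), `sentinel2` as published centre
#' wavelengths with synthesized gaussian responses (15-nm FWHM for the three
#' red-edge bands; order-of-magnitude widths elsewhere, editable in the JSON
#' config under `extdata/sensors/`).
#'
#' @param name `"landsat8"`, `"sentinel2"` or `"gf6"`.
#' @return a `sensor_def`.
#' @export
bundled_sensor <- function(name = c("landsat8", "sentinel2", "gf6")) {
  name <- match.arg(name)
  path <- system.file("extdata", "sensors", paste0(name, ".json"),
                      package = "canopysat", mustWork = TRUE)
  read_sensor_config(path)
}

#' Build the spectral response function of one band on a grid
#'
#' Boxcar bands get weight 1 at every grid point inside `[lower, upper]` and
#' 0 outside; gaussian bands get the peak-normalized response
#' `exp(-4 ln2 (lambda - center)^2 / fwhm^2)`, truncated to 0 where the
#' weight falls below 1e-4.
#'
#' @param band a [band_definition()].
#' @param grid wavelength grid, nm, uniform 1-nm step.
#' @return object of class `srf`: list with `band`, `grid`, `weights`.
#' @export
build_srf <- function(band, grid = wavelength_grid()) {
  stopifnot(inherits(band, "band_def"))
  steps <- diff(grid)
  if (any(abs(steps - 1) > 1e-9)) {
    stop("grid must have a uniform 1-nm step", call. = FALSE)
  }
  if (band$shape == "boxcar") {
    if (band$lower < min(grid) || band$upper > max(grid)) {
      stop("band support outside the wavelength grid: ", band$name,
           call. = FALSE)
    }
    w <- as.numeric(grid >= band$lower & grid <= band$upper)
  } else {
    if (band$center < min(grid) || band$center > max(grid)) {
      stop("band support outside the wavelength grid: ", band$name,
           call. = FALSE)
    }
    w <- exp(-4 * log(2) * (grid - band$center)^2 / band$fwhm^2)
    w[w < 1e-4] <- 0
  }
  if (!any(w > 0)) {
    stop("degenerate band: no positive SRF weight for ", band$name,
         call. = FALSE)
  }
  structure(list(band = band, grid = grid, weights = w), class = "srf")
}

# Trapezoidal integral of y over a uniform unit-step grid.
trapz_unit <- function(y) {
  n <- length(y)
  if (n < 2L) return(0)
  sum(y) - (y[1] + y[n]) / 2
}

#' Convolve one spectrum into one band reflectance
#'
#' Implements the band-simulation quotient: the SRF-weighted mean of the
#' spectrum, integral of `s(lambda) rho(lambda)` over the band support
#' divided by the integral of `s(lambda)`, both by the trapezoidal rule on
#' the native 1-nm grid.
#'
#' @param spectrum list with `wavelength` and `reflectance` on the SRF grid.
#' @param srf an [build_srf()] object sharing that grid.
#' @return simulated band reflectance, unitless scalar.
#' @export
resample_band <- function(spectrum, srf) {
  stopifnot(inherits(srf, "srf"))
  if (!isTRUE(all.equal(spectrum$wavelength, srf$grid))) {
    stop("spectrum and SRF are on different wavelength grids", call. = FALSE)
  }
  idx <- range(which(srf$weights > 0))
  sel <- idx[1]:idx[2]
  w <- srf$weights[sel]
  denom <- trapz_unit(w)
  if (denom <= 0) stop("degenerate band: zero total SRF weight", call. = FALSE)
  trapz_unit(w * spectrum$reflectance[sel]) / denom
}

#' Restrict a sensor to its visible/near-infrared bands
#'
#' Keeps boxcar bands whose full range lies within 400--1000 nm and
#' centre-defined bands whose centre lies within 400--1000 nm, preserving
#' order. Reproduces the published VNIR counts of the bundled sensors:
#' 5 (Landsat-8), 10 (Sentinel-2), 8 (GF-6).
#'
#' @param sensor a `sensor_def`.
#' @return a `sensor_def` with only the retained bands.
#' @export
filter_vnir_bands <- function(sensor) {
  stopifnot(inherits(sensor, "sensor_def"))
  keep <- vapply(sensor$bands, function(b) {
    if (b$shape == "boxcar") b$lower >= 400 && b$upper <= 1000
    else b$center >= 400 && b$center <= 1000
  }, logical(1))
  sensor_definition(sensor$name, sensor$bands[keep])
}

#' Simulate a satellite band table from a spectral library
#'
#' Applies [filter_vnir_bands()] (unless `vnir_only = FALSE`), builds each
#' band's SRF once on the library grid, and convolves every sample. Row
#' order follows the library.
#'
#' @param library a `spectral_library`.
#' @param sensor a `sensor_def`.
#' @param vnir_only restrict to VNIR bands first (default TRUE).
#' @return a `band_table`: data.frame with `sample_id`, `stage`,
#'   `nitrogen_mg_per_g`, then one column per band; attributes `sensor` and
#'   `band_names`.
#' @export
simulate_sensor_table <- function(library, sensor, vnir_only = TRUE) {
  stopifnot(inherits(library, "spectral_library"),
            inherits(sensor, "sensor_def"))
  if (n_samples(library) == 0L) stop("empty spectral library", call. = FALSE)
  if (vnir_only) sensor <- filter_vnir_bands(sensor)
  srfs <- lapply(sensor$bands, build_srf, grid = library$wavelength)
  vals <- vapply(srfs, function(s) {
    apply(library$reflectance, 2L, function(col) {
      resample_band(list(wavelength = library$wavelength, reflectance = col), s)
    })
  }, numeric(n_samples(library)))
  if (n_samples(library) == 1L) vals <- matrix(vals, nrow = 1L)
  colnames(vals) <- band_names(sensor)
  out <- cbind(library$metadata, as.data.frame(vals))
  rownames(out) <- NULL
  structure(out, sensor = sensor$name, band_names = band_names(sensor),
            class = c("band_table", "data.frame"))
}

#' Extract the band reflectance matrix from a band table
#' @param table a `band_table`.
#' @return numeric matrix, samples x bands.
#' @export
band_matrix <- function(table) {
  as.matrix(table[, attr(table, "band_names"), drop = FALSE])
}

#' Write / read a simulated band table as CSV
#'
#' Header `sample_id, stage, nitrogen_mg_per_g, <band names...>`; the sensor
#' name travels in a `# sensor:` comment line so round-trips preserve it.
#'
#' @param table a `band_table`.
#' @param path CSV path.
#' @return `path`, invisibly (writer); a `band_table` (reader).
#' @export
write_band_table <- function(table, path) {
  stopifnot(inherits(table, "band_table"))
  writeLines(paste0("# sensor: ", attr(table, "sensor")), path)
  readr::write_csv(as.data.frame(table), path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_band_table
#' @export
read_band_table <- function(path) {
  first <- readLines(path, n = 1L)
  sensor <- sub("^# sensor: ", "", first)
  df <- as.data.frame(readr::read_csv(path, comment = "#",
                                      show_col_types = FALSE))
  meta_cols <- c("sample_id", "stage", "nitrogen_mg_per_g")
  if (!all(meta_cols %in% names(df))) {
    stop("band table CSV lacks the metadata columns", call. = FALSE)
  }
  structure(df, sensor = sensor,
            band_names = setdiff(names(df), meta_cols),
            class = c("band_table", "data.frame"))
}
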