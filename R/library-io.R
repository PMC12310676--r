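#' Write a spectral library to CSV
#'
#' Two files are written: `spectra.csv` (first column `wavelength_nm`, one
#' column per sample) and `metadata.csv` (`sample_id`, `stage`,
#' `nitrogen_mg_per_g`). Numbers are serialized with shortest round-trip
#' representation, so write followed by read is lossless at full double
#' precision.
#'
#' @param library a `spectral_library`.
#' @param dir output directory (created if needed).
#' @return named character vector with the two file paths, invisibly.
#' @export
write_library <- function(library, dir) {
  stopifnot(inherits(library, "spectral_library"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  spectra <- data.frame(wavelength_nm = library$wavelength,
                        library$reflectance, check.names = FALSE)
  paths <- c(spectra = file.path(dir, "spectra.csv"),
             metadata = file.path(dir, "metadata.csv"))
  readr::write_csv(spectra, paths[["spectra"]])
  readr::write_csv(library$metadata, paths[["metadata"]])
  invisible(paths)
}

#' Read a spectral library from CSV
#'
#' Inverse of [write_library()]. Validates the grid (uniform step), id
#' uniqueness and spectra/metadata agreement, naming the offending sample in
#' error messages.
#'
#' @param path_spectra path to the wide spectra CSV.
#' @param path_metadata path to the metadata CSV.
#' @return a `spectral_library`.
#' @export
read_library <- function(path_spectra, path_metadata) {
  spectra <- as.data.frame(readr::read_csv(path_spectra,
                                           show_col_types = FALSE))
  meta <- as.data.frame(readr::read_csv(path_metadata, show_col_types = FALSE))
  if (names(spectra)[1] != "wavelength_nm") {
    stop("spectra CSV must start with a `wavelength_nm` column", call. = FALSE)
  }
  ids <- names(spectra)[-1]
  if (anyDuplicated(ids)) {
    stop("duplicate sample_id in spectra CSV: ", ids[duplicated(ids)][1],
         call. = FALSE)
  }
  missing_meta <- setdiff(ids, meta$sample_id)
  if (length(missing_meta)) {
    stop("metadata row missing for sample: ", missing_meta[1], call. = FALSE)
  }
  extra_meta <- setdiff(meta$sample_id, ids)
  if (length(extra_meta)) {
    stop("spectra column missing for sample: ", extra_meta[1], call. = FALSE)
  }
  wl <- spectra$wavelength_nm
  steps <- diff(wl)
  if (any(steps <= 0) || any(abs(steps - steps[1]) > 1e-9)) {
    stop("non-uniform wavelength grid in spectra CSV", call. = FALSE)
  }
  meta <- meta[match(ids, meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL
  spectral_library(wavelength = wl,
                   reflectance = as.matrix(spectra[, -1, drop = FALSE]),
                   metadata = meta)
}
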