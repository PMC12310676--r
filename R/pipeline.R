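#' Pipeline configuration
#'
#' One config drives the whole analysis from a single seed: generate seeded
#' libraries per stage, smooth, convolve to each sensor's VNIR bands, screen
#' band pairs, run the PLSR ablations, and train/evaluate the SVM and BPNN
#' estimators on the shared per-stage splits.
#'
#' @param seed master seed; every random stream derives from it.
#' @param stages phenological stages to simulate.
#' @param n_per_stage samples per stage; must equal
#'   `n_train + n_validation`.
#' @param sensors bundled sensor names (see [bundled_sensor()]).
#' @param window,polyorder Savitzky-Golay smoothing parameters.
#' @param n_train,n_validation split sizes.
#' @param out_dir output directory for all artifacts.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, stages = canopysat::stages(),
                            n_per_stage = 100L,
                            sensors = c("landsat8", "sentinel2", "gf6"),
                            window = 15L, polyorder = 3L,
                            n_train = 60L, n_validation = 40L,
                            out_dir = "results/pipeline") {
  if (n_per_stage != n_train + n_validation) {
    stop("n_per_stage must equal n_train + n_validation", call. = FALSE)
  }
  known <- c("landsat8", "sentinel2", "gf6")
  bad <- setdiff(sensors, known)
  if (length(bad)) stop("unknown sensor: ", bad[1], call. = FALSE)
  lapply(stages, match_stage)
  structure(list(seed = seed, stages = stages, n_per_stage = n_per_stage,
                 sensors = sensors, window = window, polyorder = polyorder,
                 n_train = n_train, n_validation = n_validation,
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes generate, smooth, resample, screen, PLSR ablation and model
#' evaluation in order, writing every intermediate artifact under
#' `config$out_dir` and a manifest (config, seed, file checksums) as
#' `manifest.json`. Reruns with the same config produce identical checksums.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress progress messages.
#' @return the manifest, invisibly (a list).
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(...)
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  files <- character()

  say("generating and smoothing spectral libraries")
  libraries <- list()
  for (i in seq_along(config$stages)) {
    stage <- config$stages[i]
    lib <- generate_dataset(stage, config$n_per_stage,
                            seed = derive_seed(config$seed, 1000L + i))
    lib <- smooth_library(lib, config$window, config$polyorder)
    libraries[[stage]] <- lib
    paths <- write_library(lib, file.path(out, "libraries", stage))
    files <- c(files, paths)
  }

  say("convolving to sensor bands")
  tables <- list()
  for (s in config$sensors) {
    sensor <- bundled_sensor(s)
    tables[[s]] <- list()
    for (stage in config$stages) {
      tab <- simulate_sensor_table(libraries[[stage]], sensor)
      tables[[s]][[stage]] <- tab
      p <- file.path(out, "band_tables", sprintf("%s_%s.csv", s, stage))
      dir.create(dirname(p), recursive = TRUE, showWarnings = FALSE)
      write_band_table(tab, p)
      files <- c(files, p)
    }
  }

  say("screening band pairs")
  for (s in config$sensors) {
    for (stage in config$stages) {
      res <- screen_band_pairs(tables[[s]][[stage]])
      p <- file.path(out, "screening", sprintf("%s_%s.csv", s, stage))
      dir.create(dirname(p), recursive = TRUE, showWarnings = FALSE)
      screening_matrix_export(res, p, sort_by_abs_r = TRUE)
      files <- c(files, p)
    }
  }

  say("PLSR band-removal ablations")
  plsr_rows <- list()
  for (s in config$sensors) {
    for (stage in config$stages) {
      tab <- tables[[s]][[stage]]
      bn <- attr(tab, "band_names")
      plsr_rows[[paste(s, stage)]] <-
        ablation_table(tab, base_bands = bn, removable = bn)
    }
  }
  plsr_report <- do.call(rbind, plsr_rows)
  rownames(plsr_report) <- NULL
  p <- file.path(out, "plsr_ablation.csv")
  readr::write_csv(plsr_report, p)
  files <- c(files, p)

  say("training and evaluating SVM / BPNN estimators")
  spec <- split_spec(config$n_train, config$n_validation,
                     seed = derive_seed(config$seed, 2000L))
  report <- suppressWarnings(
    evaluate_all(tables, spec, seed = derive_seed(config$seed, 3000L)))
  p <- file.path(out, "evaluation.csv")
  readr::write_csv(report, p)
  files <- c(files, p)
  preds <- attr(report, "predictions")
  for (stage in config$stages) {
    p <- file.path(out, "scatter", sprintf("%s.csv", stage))
    dir.create(dirname(p), recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(preds[preds$stage == stage, , drop = FALSE], p)
    files <- c(files, p)
  }

  files <- unname(files)
  manifest <- list(
    config = unclass(config),
    config_hash = digest_config(config),
    files = data.frame(path = sub(paste0("^", out, "/?"), "", files),
                       md5 = unname(tools::md5sum(files)),
                       stringsAsFactors = FALSE)
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("done: ", length(files), " artifacts under ", out)
  invisible(manifest)
}

digest_config <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(paste(deparse(unclass(config)), collapse = ""), tmp)
  unname(tools::md5sum(tmp))
}

#' Summarize a completed pipeline run
#'
#' Aggregates the evaluation report to per-sensor means across phenological
#' stages (arithmetic mean over stages, the convention used when quoting a
#' sensor's "average" accuracy), for one model type.
#'
#' @param run_dir the pipeline output directory.
#' @param model model type to aggregate (default `"SVM"`).
#' @return data.frame, one row per sensor: mean training/validation R-squared
#'   and RMSE across stages.
#' @export
report_summary <- function(run_dir, model = "SVM") {
  manifest_path <- file.path(run_dir, "manifest.json")
  if (!file.exists(manifest_path)) {
    stop("incomplete run: missing manifest.json in ", run_dir, call. = FALSE)
  }
  manifest <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  expected <- file.path(run_dir, manifest$files$path)
  missing <- expected[!file.exists(expected)]
  if (length(missing)) {
    stop("incomplete run: missing artifacts:\n  ",
         paste(missing, collapse = "\n  "), call. = FALSE)
  }
  ev <- as.data.frame(readr::read_csv(file.path(run_dir, "evaluation.csv"),
                                      show_col_types = FALSE))
  ev <- ev[ev$model == model, , drop = FALSE]
  agg <- function(split, col) {
    sub <- ev[ev$split == split, , drop = FALSE]
    tapply(sub[[col]], sub$sensor, mean)
  }
  sensors <- sort(unique(ev$sensor))
  data.frame(sensor = sensors,
             r2_train = as.numeric(agg("training", "r2")[sensors]),
             rmse_train = as.numeric(agg("training", "rmse")[sensors]),
             r2_validation = as.numeric(agg("validation", "r2")[sensors]),
             rmse_validation = as.numeric(agg("validation", "rmse")[sensors]),
             stringsAsFactors = FALSE)
}
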