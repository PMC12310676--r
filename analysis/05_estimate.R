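#!/usr/bin/env Rscript
# Step 5: train the SVM and BPNN nitrogen estimators on all VNIR bands per
# sensor and stage, with one shared seeded 60/40 split per stage so sensor
# and model comparisons are paired, and write the 36-row evaluation report
# plus per-stage measured-vs-predicted scatter data.

library(canopysat)
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[1]) else 1L
out <- "results/analysis"

tables <- lapply(c(landsat8 = "landsat8", sentinel2 = "sentinel2",
                   gf6 = "gf6"), function(s) {
  tabs <- lapply(stages(), function(stage) {
    read_band_table(file.path(out, "band_tables",
                              sprintf("%s_%s.csv", s, stage)))
  })
  names(tabs) <- stages()
  tabs
})

spec <- split_spec(60, 40, seed = derive_seed(seed, 2000L))
report <- suppressWarnings(
  evaluate_all(tables, spec, seed = derive_seed(seed, 3000L)))
readr::write_csv(report, file.path(out, "evaluation.csv"))
preds <- attr(report, "predictions")
dir.create(file.path(out, "scatter"), showWarnings = FALSE)
for (stage in stages()) {
  readr::write_csv(preds[preds$stage == stage, ],
                   file.path(out, "scatter", paste0(stage, ".csv")))
}
print(report, digits = 3)
cat("evaluation written to", file.path(out, "evaluation.csv"), "\n")
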