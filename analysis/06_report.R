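#!/usr/bin/env Rscript
# Step 6: aggregate the evaluation to per-sensor means across the three
# phenological stages (the "average R2 / RMSE" convention) and rank the
# sensors. On the synthetic libraries the red-edge-equipped sensors
# (Sentinel-2, GF-6) outrank Landsat-8, mirroring the field study's sensor
# ordering; absolute values are properties of the generator, not of any
# field dataset.

library(canopysat)
out <- "results/analysis"

ev <- as.data.frame(readr::read_csv(file.path(out, "evaluation.csv"),
                                    show_col_types = FALSE))
for (model in c("SVM", "BPNN")) {
  sub <- ev[ev$model == model, ]
  agg <- function(split, col) {
    tapply(sub[[col]][sub$split == split], sub$sensor[sub$split == split],
           mean)
  }
  summ <- data.frame(r2_train = agg("training", "r2"),
                     rmse_train = agg("training", "rmse"),
                     r2_val = agg("validation", "r2"),
                     rmse_val = agg("validation", "rmse"))
  cat("\n", model, "— per-sensor means across stages:\n")
  print(round(summ[order(-summ$r2_val), ], 3))
}
readr::write_csv(cbind(sensor = rownames(summ), summ),
                 file.path(out, "sensor_summary.csv"))
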