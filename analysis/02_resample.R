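#!/usr/bin/env Rscript
# Step 2: convolve every library with the three sensors' spectral response
# functions, keeping the VNIR band subsets (5 Landsat-8 / 10 Sentinel-2 /
# 8 GF-6 bands), and write the simulated band tables.

library(canopysat)
out <- "results/analysis"

for (s in c("landsat8", "sentinel2", "gf6")) {
  sensor <- bundled_sensor(s)
  vnir <- filter_vnir_bands(sensor)
  cat(sprintf("%s: %d VNIR bands (%s)\n", sensor$name, length(vnir$bands),
              paste(band_names(vnir), collapse = ", ")))
  for (stage in stages()) {
    lib <- read_library(file.path(out, "libraries", stage, "spectra.csv"),
                        file.path(out, "libraries", stage, "metadata.csv"))
    tab <- simulate_sensor_table(lib, sensor)
    p <- file.path(out, "band_tables", sprintf("%s_%s.csv", s, stage))
    dir.create(dirname(p), recursive = TRUE, showWarnings = FALSE)
    write_band_table(tab, p)
  }
}
cat("band tables written under", file.path(out, "band_tables"), "\n")
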