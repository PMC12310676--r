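# Golden values: published band parameters of the three sensors.
landsat8_golden <- list(
  coastal = c(433, 453), blue = c(450, 515), green = c(525, 600),
  red = c(630, 680), NIR = c(845, 885), SWIR1 = c(1560, 1660),
  SWIR2 = c(2100, 2300), cirrus = c(1360, 1390))
sentinel2_centers <- c(coastal = 443, blue = 490, green = 560, red = 665,
                       RE1 = 705, RE2 = 740, RE3 = 783, NIR1 = 842,
                       NIR2 = 865, watervapor = 945, cirrus = 1375,
                       SWIR1 = 1610, SWIR2 = 2190)
gf6_golden <- list(
  blue = c(450, 520), green = c(520, 590), red = c(630, 690),
  NIR = c(770, 890), RE1 = c(690, 730), RE2 = c(730, 770),
  PE = c(400, 450), YE = c(590, 630))

test_that("bundled sensor configs reproduce the published band tables", {
  l8 <- bundled_sensor("landsat8")
  expect_identical(band_names(l8), names(landsat8_golden))
  for (b in l8$bands) {
    expect_identical(b$shape, "boxcar")
    expect_equal(c(b$lower, b$upper), landsat8_golden[[b$name]])
  }
  s2 <- bundled_sensor("sentinel2")
  expect_identical(band_names(s2), names(sentinel2_centers))
  for (b in s2$bands) {
    expect_identical(b$shape, "gaussian")
    expect_equal(b$center, unname(sentinel2_centers[b$name]))
    expect_gt(b$fwhm, 0)
  }
  # red-edge responses are the narrow 15-nm synthesized gaussians
  for (re in c("RE1", "RE2", "RE3")) {
    expect_equal(s2$bands[[which(band_names(s2) == re)]]$fwhm, 15)
  }
  g6 <- bundled_sensor("gf6")
  expect_identical(band_names(g6), names(gf6_golden))
  for (b in g6$bands) {
    expect_equal(c(b$lower, b$upper), gf6_golden[[b$name]])
  }
})

test_that("VNIR filtering yields the published 5/10/8 band counts", {
  l8 <- filter_vnir_bands(bundled_sensor("landsat8"))
  expect_identical(band_names(l8),
                   c("coastal", "blue", "green", "red", "NIR"))
  s2 <- filter_vnir_bands(bundled_sensor("sentinel2"))
  expect_length(s2$bands, 10L)
  expect_true(all(vapply(s2$bands, `[[`, numeric(1), "center") <= 1000))
  g6 <- filter_vnir_bands(bundled_sensor("gf6"))
  expect_length(g6$bands, 8L)
})

test_that("SRF construction matches the boxcar and gaussian definitions", {
  grid <- wavelength_grid()
  nir <- build_srf(band_definition("NIR", "boxcar", 845, 885), grid)
  expect_equal(sum(nir$weights == 1), 41L)
  expect_equal(sum(nir$weights != 0), 41L)
  g <- build_srf(band_definition("RE1", "gaussian", center = 705, fwhm = 30),
                 grid)
  expect_equal(g$weights[grid == 705], 1)
  expect_equal(g$weights[grid == 690], 0.5, tolerance = 1e-9)
  expect_equal(g$weights[grid == 720], 0.5, tolerance = 1e-9)
  expect_true(all(g$weights >= 0))
  expect_error(build_srf(band_definition("bad", "boxcar", 345, 400),
                         grid = 350:2500), "wavelength")
})

test_that("band resampling matches closed forms and the trapezoid oracle", {
  grid <- wavelength_grid()
  srf <- build_srf(band_definition("NIR", "boxcar", 845, 885), grid)
  flat <- list(wavelength = grid, reflectance = rep(0.5, length(grid)))
  expect_equal(resample_band(flat, srf), 0.5, tolerance = 1e-12)
  ramp <- list(wavelength = grid, reflectance = grid / 2500)
  expect_equal(resample_band(ramp, srf), 865 / 2500, tolerance = 1e-6)
  # explicit trapezoid oracle on the support
  sel <- which(srf$weights > 0)
  oracle <- trapz_oracle(srf$weights[sel] * ramp$reflectance[sel]) /
    trapz_oracle(srf$weights[sel])
  expect_equal(resample_band(ramp, srf), oracle, tolerance = 1e-12)
})

test_that("resampling is normalized, linear and bounded on all bundled bands", {
  grid <- wavelength_grid()
  sensors <- lapply(c("landsat8", "sentinel2", "gf6"), bundled_sensor)
  srfs <- unlist(lapply(sensors, function(s) {
    lapply(filter_vnir_bands(s)$bands, build_srf, grid = grid)
  }), recursive = FALSE)
  expect_length(srfs, 23L)
  set.seed(4)
  for (rep in 1:10) {
    r1 <- pmin(pmax(0.3 + cumsum(rnorm(length(grid), 0, 0.001)), 0), 1)
    r2 <- pmin(pmax(0.5 + 0.2 * sin(grid / 150), 0), 1)
    a <- runif(1); b <- runif(1)
    for (srf in srfs) {
      s1 <- list(wavelength = grid, reflectance = r1)
      s2 <- list(wavelength = grid, reflectance = r2)
      mix <- list(wavelength = grid, reflectance = a * r1 + b * r2)
      v1 <- resample_band(s1, srf); v2 <- resample_band(s2, srf)
      expect_equal(resample_band(mix, srf), a * v1 + b * v2,
                   tolerance = 1e-9)
      sel <- srf$weights > 0
      expect_gte(v1, min(r1[sel]) - 1e-12)
      expect_lte(v1, max(r1[sel]) + 1e-12)
    }
  }
  # constant-spectrum preservation per band
  const <- list(wavelength = grid, reflectance = rep(0.3, length(grid)))
  for (srf in srfs) {
    expect_equal(resample_band(const, srf), 0.3, tolerance = 1e-9)
  }
})

test_that("simulated band tables have the right shape and propagate constants", {
  lib <- generate_dataset("NGS", 10, seed = 2)
  tab <- simulate_sensor_table(lib, bundled_sensor("sentinel2"))
  expect_s3_class(tab, "band_table")
  expect_equal(dim(band_matrix(tab)), c(10L, 10L))
  expect_identical(tab$sample_id, lib$metadata$sample_id)
  flat <- tiny_library(1, value = 0.3)
  for (s in c("landsat8", "sentinel2", "gf6")) {
    tf <- simulate_sensor_table(flat, bundled_sensor(s))
    expect_equal(unname(as.numeric(band_matrix(tf))),
                 rep(0.3, length(attr(tf, "band_names"))), tolerance = 1e-9)
  }
})

test_that("band table CSV round-trips with sensor metadata", {
  lib <- generate_dataset("ASS", 4, seed = 9)
  tab <- simulate_sensor_table(lib, bundled_sensor("gf6"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_band_table(tab, path)
  back <- read_band_table(path)
  expect_identical(attr(back, "sensor"), attr(tab, "sensor"))
  expect_identical(attr(back, "band_names"), attr(tab, "band_names"))
  expect_equal(band_matrix(back), band_matrix(tab))
})
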