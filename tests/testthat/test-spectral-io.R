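# Reading, stitching, resampling, and panel calibration.

test_that("a three-detector file splits into segments matching the instrument ranges", {
  f <- write_svc_fixture(withr::local_tempfile(fileext = ".sig"))
  raw <- read_spectrum_file(f)
  expect_length(raw$segments, 3)
  ids <- vapply(raw$segments, `[[`, character(1), "detector")
  expect_equal(ids, c("VNIR", "SWIR1", "SWIR2"))
  rng <- t(vapply(raw$segments, function(s) range(s$wavelength), numeric(2)))
  expect_equal(rng[1, ], c(350, 999.5), tolerance = 1e-6)
  expect_true(rng[2, 1] < 1000 && rng[2, 2] <= 1890)
  expect_true(rng[3, 1] < 1890 && rng[3, 2] == 2500)
  expect_equal(raw$meta$treatment, "aCO2")
  expect_equal(raw$meta$tree_id, "a1_t1")
})

test_that("a single-segment 1 nm file reads as one segment and round-trips", {
  wl <- 350:2500
  val <- 0.1 + 0.2 * abs(sin(wl / 500))
  f <- write_csv_spectrum(withr::local_tempfile(fileext = ".csv"), wl, val)
  raw <- read_spectrum_file(f)
  expect_length(raw$segments, 1)
  s <- resample_1nm(stitch(raw))
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_spectrum(s, f2)
  s2 <- resample_1nm(stitch(read_spectrum_file(f2)))
  expect_equal(s2$reflectance, s$reflectance, tolerance = 1e-12)
})

test_that("a duplicated wavelength row is a parse error naming the wavelength", {
  wl <- c(350:1000, 1000, 1001:2500)
  f <- write_csv_spectrum(withr::local_tempfile(fileext = ".csv"),
                          wl, rep(0.2, length(wl)))
  expect_error(read_spectrum_file(f), "duplicated wavelength 1000")
})

test_that("segments that agree on their overlap stitch identically under both policies", {
  vnir <- seq(350, 1000, 0.5)
  swir <- seq(990, 1890, 0.5)
  fun <- function(wl) 0.3 + wl / 10000
  raw <- leafspec:::new_raw_spectrum(list(
    list(detector = "VNIR", wavelength = vnir, value = fun(vnir)),
    list(detector = "SWIR1", wavelength = swir, value = fun(swir))))
  for (pol in c("cut", "rescale")) {
    st <- stitch(raw, pol)
    expect_equal(st$value, fun(st$wavelength), tolerance = 1e-12)
    expect_true(all(diff(st$wavelength) > 0))
  }
})

test_that("jump correction rescales a later segment by the overlap mean ratio", {
  vnir <- seq(350, 1005, 1)
  swir <- seq(995, 1890, 1)
  raw <- leafspec:::new_raw_spectrum(list(
    list(detector = "VNIR", wavelength = vnir, value = rep(0.40, length(vnir))),
    list(detector = "SWIR1", wavelength = swir, value = rep(0.50, length(swir)))))
  st <- stitch(raw, "rescale")
  expect_equal(st$scale, c(1, 0.8))
  expect_equal(unique(st$value), 0.40)
})

test_that("a three-segment fixture stitches to one continuous 350-2500 nm series", {
  f <- write_svc_fixture(withr::local_tempfile(fileext = ".sig"))
  st <- stitch(read_spectrum_file(f))
  expect_equal(range(st$wavelength), c(350, 2500))
  expect_true(all(diff(st$wavelength) > 0))
})

test_that("segment gaps above 5 nm are a stitching error", {
  raw <- leafspec:::new_raw_spectrum(list(
    list(detector = "VNIR", wavelength = seq(350, 990, 1), value = rep(0.3, 641)),
    list(detector = "SWIR1", wavelength = seq(1000, 1890, 1), value = rep(0.3, 891))))
  expect_error(stitch(raw), "gap of 10")
})

test_that("resampling interpolates linearly and is exact on the integer grid", {
  # identity on grid input
  s <- random_spectrum(4)
  expect_identical(resample_1nm(s)$reflectance, s$reflectance)
  # idempotence
  expect_identical(resample_1nm(resample_1nm(s))$reflectance,
                   resample_1nm(s)$reflectance)
  # linear midpoint
  st <- list(wavelength = c(349, 400, 402, 2501),
             value = c(0.1, 0.1, 0.3, 0.3))
  expect_equal(resample_1nm(st)$reflectance[401 - 349], 0.2)
  # native-resolution fixture yields the full 2151-point grid
  f <- write_svc_fixture(withr::local_tempfile(fileext = ".sig"))
  out <- resample_1nm(stitch(read_spectrum_file(f)))
  expect_length(out$reflectance, 2151)
  # coverage shortfall beyond 5 nm errors
  expect_error(resample_1nm(list(wavelength = 360:2500,
                                 value = rep(0.2, 2141))), "misses")
})

test_that("a constant spectrum survives stitch and resample exactly under any policy", {
  f <- write_svc_fixture(withr::local_tempfile(fileext = ".sig"),
                         value_fun = function(wl) rep(0.271, length(wl)))
  for (pol in c("cut", "rescale")) {
    out <- resample_1nm(stitch(read_spectrum_file(f), pol))
    expect_equal(out$reflectance, rep(0.271, 2151), tolerance = 1e-12)
  }
})

test_that("panel calibration multiplies and an identity panel is a no-op", {
  s <- flat_spectrum(0.5)
  unit <- panel_calibration(c(350, 2500), c(1, 1))
  expect_equal(to_absolute(s, unit)$reflectance, s$reflectance)
  p98 <- panel_calibration(c(350, 2500), c(0.98, 0.98))
  expect_equal(to_absolute(s, p98)$reflectance, rep(0.49, 2151))
  # wavelength-dependent panel: elementwise ratio recovers the panel curve
  wl <- seq(350, 2500, 10)
  pan <- panel_calibration(wl, 0.9 + 0.05 * sin(wl / 400))
  s2 <- random_spectrum(7)
  abs_s <- to_absolute(s2, pan)
  ratio <- abs_s$reflectance / s2$reflectance
  pan_on_grid <- approx(pan$wavelength_nm, pan$panel_reflectance,
                        xout = spectrum_grid())$y
  expect_equal(ratio, pan_on_grid, tolerance = 1e-12)
  expect_error(panel_calibration(c(350, 2500), c(-0.1, 1)), "positive")
})

test_that("metadata passes unchanged through stitch, resample, and calibration", {
  f <- write_svc_fixture(withr::local_tempfile(fileext = ".sig"))
  raw <- read_spectrum_file(f)
  s <- to_absolute(resample_1nm(stitch(raw, "rescale")),
                   panel_calibration(c(350, 2500), c(0.99, 0.99)))
  expect_identical(s$meta[c("treatment", "array_id", "tree_id", "date")],
                   raw$meta[c("treatment", "array_id", "tree_id", "date")])
})

test_that("values above one are flagged and retained, clipped only at 1.5 and 0", {
  r <- rep(0.5, 2151); r[100] <- 1.2; r[200] <- 1.9
  s <- new_spectrum(r)
  expect_true(s$flag_over_one)
  expect_equal(s$reflectance[100], 1.2)
  expect_equal(s$reflectance[200], 1.5)
  expect_false(flat_spectrum(0.3)$flag_over_one)
})

test_that("load_set preprocesses a manifest and counts treatments", {
  dir <- withr::local_tempdir()
  n <- 0
  rows <- list()
  for (trt in c("aCO2", "eCO2")) for (i in 1:3) {
    n <- n + 1
    f <- file.path(dir, sprintf("s%d.sig", n))
    write_svc_fixture(f, value_fun = function(wl) 0.2 + 0.001 * i, header = character())
    rows[[n]] <- data.frame(path = basename(f), treatment = trt,
                            array_id = paste0(substr(trt, 1, 1), "1"),
                            tree_id = paste0(substr(trt, 1, 1), "1_t1"),
                            date = "2023-07-25", leaf_index = i)
  }
  manifest <- file.path(dir, "manifest.csv")
  utils::write.csv(do.call(rbind, rows), manifest, row.names = FALSE)
  set <- load_set(manifest)
  expect_equal(n_spectra(set), 6)
  expect_equal(as.numeric(table(set$meta$treatment)), c(3, 3))

  # metadata missing for a file -> error naming it
  bad <- do.call(rbind, rows)
  bad$treatment[2] <- NA
  utils::write.csv(bad, manifest, row.names = FALSE)
  expect_error(load_set(manifest), "s2.sig")

  # empty manifest -> explicit error
  utils::write.csv(bad[0, ], manifest, row.names = FALSE)
  expect_error(load_set(manifest), "empty")
})

test_that("a spectrum set round-trips through the wide CSV to 1e-9", {
  set <- simulate_campaign(tiny_config())
  f <- withr::local_tempfile(fileext = ".csv")
  write_spectrum_set(set, f)
  back <- read_spectrum_set(f)
  expect_lt(max(abs(back$reflectance - set$reflectance)), 1e-9)
  expect_equal(back$meta$tree_id, set$meta$tree_id)
  expect_equal(back$meta$treatment, set$meta$treatment)
})
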