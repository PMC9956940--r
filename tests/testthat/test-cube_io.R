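test_that("ENVI write/read round-trips values, shape and wavelengths", {
  cube <- make_test_cube(integer_values = TRUE)
  for (il in c("bsq", "bil", "bip")) {
    hdr <- withr::local_tempfile(fileext = ".hdr")
    write_envi_cube(cube, hdr, interleave = il, data_type = 12L)
    back <- read_envi_cube(hdr, geometry = imaging_geometry(pixel_pitch_cm = 0.05))
    expect_identical(dim(back$values), dim(cube$values), info = il)
    expect_equal(back$values, cube$values, tolerance = 0, info = il)
    expect_equal(back$wavelengths_nm, cube$wavelengths_nm)
  }
  # float32 path keeps values within single precision
  hdr <- withr::local_tempfile(fileext = ".hdr")
  fcube <- make_test_cube()
  write_envi_cube(fcube, hdr, interleave = "bil", data_type = 4L)
  expect_equal(read_envi_cube(hdr)$values, fcube$values, tolerance = 1e-6)
})

test_that("all interleaves of one scene read to the same cube, matching an independent writer", {
  cube <- make_test_cube(rows = 3L, cols = 5L, integer_values = TRUE)
  d <- dim(cube$values)
  # independent flat-file writer: explicit nested loops, no shared code path
  write_flat <- function(path, order_fun) {
    con <- file(path, "wb")
    on.exit(close(con))
    v <- integer(0)
    for (trip in order_fun) v <- c(v, cube$values[trip[1], trip[2], trip[3]])
    writeBin(as.integer(v), con, size = 2L, endian = "little")
  }
  bip_order <- list()
  for (l in 1:d[1]) for (s in 1:d[2]) for (b in 1:d[3]) {
    bip_order[[length(bip_order) + 1L]] <- c(l, s, b)
  }
  bsq_order <- list()
  for (b in 1:d[3]) for (l in 1:d[1]) for (s in 1:d[2]) {
    bsq_order[[length(bsq_order) + 1L]] <- c(l, s, b)
  }
  hdr_for <- function(il, raster) {
    hdr <- paste0(raster, ".hdr")
    writeLines(c("ENVI", paste0("samples = ", d[2]),
                 paste0("lines = ", d[1]), paste0("bands = ", d[3]),
                 "data type = 2", paste0("interleave = ", il),
                 "byte order = 0",
                 paste0("wavelength = {",
                        paste(cube$wavelengths_nm, collapse = ", "), "}")),
               hdr)
    hdr
  }
  f_bip <- withr::local_tempfile()
  f_bsq <- withr::local_tempfile()
  write_flat(f_bip, bip_order)
  write_flat(f_bsq, bsq_order)
  got_bip <- read_envi_cube(hdr_for("bip", f_bip), f_bip)
  got_bsq <- read_envi_cube(hdr_for("bsq", f_bsq), f_bsq)
  expect_equal(got_bip$values, cube$values, tolerance = 0)
  expect_equal(got_bsq$values, cube$values, tolerance = 0)
})

test_that("contradictory or missing header fields raise named format errors", {
  raster <- withr::local_tempfile()
  writeBin(as.integer(rep(1L, 4 * 4 * 16)), raster, size = 2L,
           endian = "little")
  hdr <- paste0(raster, ".hdr")
  # 16 bands declared, 15 wavelengths listed
  writeLines(c("ENVI", "samples = 4", "lines = 4", "bands = 16",
               "data type = 2", "interleave = bsq",
               paste0("wavelength = {",
                      paste(imec_16band_nm[1:15], collapse = ", "), "}")),
             hdr)
  expect_error(read_envi_cube(hdr, raster), "dimension error.*15 wavelengths")
  writeLines(c("ENVI", "samples = 4", "lines = 4",
               "data type = 2", "interleave = bsq"), hdr)
  expect_error(read_envi_cube(hdr, raster), "missing field 'bands'")
  writeLines(c("ENVI", "samples = 4", "lines = 4", "bands = 16",
               "data type = 2", "interleave = weird"), hdr)
  expect_error(read_envi_cube(hdr, raster), "format error.*interleave")
})

test_that("white correction follows the flat-field formula at its anchor points", {
  geom <- imaging_geometry()
  white <- const_cube(4000)
  dark <- const_cube(100)
  # raw == white, no dark: everything equals the board reflectance
  cal <- calibrate_reflectance(const_cube(4000), white, geometry = geom)
  expect_true(all(cal$values == 0.98))
  expect_true(cal$calibrated)
  # raw == dark: zero point
  cal0 <- calibrate_reflectance(const_cube(100), white, dark, geom)
  expect_true(all(cal0$values == 0))
  # raw at the midpoint of the dynamic range: 0.98 * 0.5 = 0.49
  mid <- const_cube(100 + 0.5 * (4000 - 100))
  calm <- calibrate_reflectance(mid, white, dark, geom)
  expect_equal(unique(as.vector(calm$values)), 0.49)
})

test_that("calibration clips to the ceiling, broadcasts a single white spectrum, and is idempotent", {
  geom <- imaging_geometry()
  # raw above white: clipped at 1.10, not an error
  hot <- calibrate_reflectance(const_cube(6000), const_cube(4000),
                               geometry = geom)
  expect_true(all(hot$values == 1.10))
  # 1 x 1 x bands white spectrum broadcast over the scene
  wspec <- spectral_cube(array(seq(1000, 4000, length.out = 16),
                               dim = c(1, 1, 16)), pixel_pitch_cm = 0.05)
  raw <- make_test_cube(integer_values = TRUE)
  cal <- calibrate_reflectance(raw, wspec, geometry = geom)
  b <- 7L
  expect_equal(cal$values[2, 3, b],
               min(0.98 * raw$values[2, 3, b] / wspec$values[1, 1, b], 1.10))
  # calibrating calibrated output against a constant 0.98 white is identity
  again <- calibrate_reflectance(cal, const_cube(0.98, rows = 4, cols = 4),
                                 geometry = geom)
  expect_equal(again$values, cal$values, tolerance = 1e-12)
})

test_that("non-positive white minus dark reports the count of bad entries", {
  expect_error(
    calibrate_reflectance(const_cube(50, rows = 2, cols = 2),
                          const_cube(100, rows = 2, cols = 2),
                          const_cube(100, rows = 2, cols = 2)),
    "calibration error.*64 pixel-band entries")
})

test_that("demosaicing maps mosaic tiles to bands and inverts exactly", {
  # constant field: every band constant
  cube <- demosaic_snapshot(matrix(7, 8, 8))
  expect_identical(dim(cube$values), c(2L, 2L, 16L))
  expect_true(all(cube$values == 7))
  expect_equal(cube$pixel_pitch_cm, 0.05 * 4)
  # indicator tile (0,0): only band 1 lights up
  m <- matrix(0, 8, 8)
  m[seq(1, 8, 4), seq(1, 8, 4)] <- 7
  ind <- demosaic_snapshot(m)
  expect_true(all(ind$values[, , 1] == 7))
  expect_true(all(ind$values[, , -1] == 0))
  # random mosaic equals a nested-loop per-offset extraction oracle
  mos <- withr::with_seed(9, matrix(stats::runif(16 * 16), 16, 16))
  cube <- demosaic_snapshot(mos)
  for (b in 0:15) {
    ro <- b %/% 4L
    co <- b %% 4L
    oracle <- matrix(0, 4, 4)
    for (i in 1:4) for (j in 1:4) {
      oracle[i, j] <- mos[(i - 1) * 4 + ro + 1, (j - 1) * 4 + co + 1]
    }
    expect_equal(cube$values[, , b + 1], oracle)
  }
  # re-interleaving reconstructs the mosaic bit-exactly
  expect_identical(snapshot_mosaic(cube), mos)
  expect_error(demosaic_snapshot(matrix(0, 9, 8)), "dimension error")
})

test_that("multi-band TIFF reads to the same cube as ENVI", {
  cube <- make_test_cube(integer_values = TRUE)
  tif <- withr::local_tempfile(fileext = ".tif")
  pages <- lapply(1:16, function(b) cube$values[, , b] / 65535)
  tiff::writeTIFF(pages, tif, bits.per.sample = 16L)
  got <- read_tiff_cube(tif)
  expect_equal(got$values, cube$values, tolerance = 0)
  expect_error(read_tiff_cube(tif, wavelengths_nm = imec_16band_nm[1:8]),
               "dimension error")
})
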