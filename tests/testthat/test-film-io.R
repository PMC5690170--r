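test_that("film TIFF write/read round trip is lossless for 12-bit data", {
  set.seed(10)
  px <- matrix(sample(0:4095, 40 * 30, replace = TRUE), 40, 30)
  scan <- film_scan(px)
  path <- withr::local_tempfile(fileext = ".tif")
  write_film_tiff(scan, path)
  back <- read_film_tiff(path)
  expect_identical(back$pixels, matrix(as.numeric(px), 40, 30))
  expect_equal(back$bit_depth, 12L)  # 12-bit data in 16-bit container
  expect_equal(back$dpi, 75)         # no metadata -> fallback
  expect_match(paste(back$steps, collapse = "; "), "fallback")
})

test_that("RGB scans reduce to the red channel, logged", {
  path <- withr::local_tempfile(fileext = ".tif")
  status <- system2("python", c("-c", shQuote(sprintf(
    "import numpy as np, tifffile; rng = np.random.default_rng(11); tifffile.imwrite('%s', rng.integers(0, 65536, size=(20,20,3), dtype=np.uint16), photometric='rgb')",
    path))))
  expect_equal(status, 0L)
  truth <- tiff::readTIFF(path, as.is = TRUE)  # [0,1] for multi-channel
  back <- read_film_tiff(path)
  expect_equal(back$pixels, round(truth[, , 1] * 65535))
  expect_match(paste(back$steps, collapse = "; "), "red channel")
})

test_that("dpi metadata yields the physical pixel pitch 25.4/dpi", {
  # fixture with embedded 75 dpi resolution tags, written by tifffile
  path <- withr::local_tempfile(fileext = ".tif")
  status <- system2("python", c("-c", shQuote(sprintf(
    "import numpy as np, tifffile; tifffile.imwrite('%s', (np.arange(400, dtype=np.uint16).reshape(20,20)*10)%%4096, resolution=(75,75), resolutionunit='INCH')",
    path))))
  expect_equal(status, 0L)
  scan <- read_film_tiff(path)
  expect_equal(scan$dpi, 75)
  expect_equal(scan_pixel_spacing(scan), 25.4 / 75)
  expect_equal(scan_pixel_spacing(scan), 0.33867, tolerance = 1e-4)
  expect_match(paste(scan$steps, collapse = "; "), "metadata")
})

test_that("ROI handling crops and rejects malformed requests", {
  px <- matrix(rep(0:4095, length.out = 600), 30, 20)
  path <- withr::local_tempfile(fileext = ".tif")
  write_film_tiff(film_scan(px), path)
  crop <- read_film_tiff(path, roi = c(5, 14, 3, 12))
  expect_equal(dim(crop$pixels), c(10L, 10L))
  expect_equal(crop$pixels, matrix(as.numeric(px[5:14, 3:12]), 10, 10))
  expect_error(read_film_tiff(path, roi = c(10, 5, 1, 10)), "ROI")
  expect_error(read_film_tiff(path, roi = c(1, 40, 1, 10)), "ROI")
  expect_error(read_film_tiff("no/such/file.tif"), "not found")
})

test_that("roi_mean_pixel returns patch statistics", {
  scan <- film_scan(matrix(1000, 10, 10))
  s <- roi_mean_pixel(scan)
  expect_equal(s$mean, 1000)
  expect_equal(s$sd, 0)
  two <- film_scan(matrix(c(1000, 2000), 10, 10))
  expect_equal(roi_mean_pixel(two)$mean, 1500)
  # noisy patch: sample mean within 4 sigma / sqrt(n) of truth
  set.seed(12)
  n <- 100
  noisy <- film_scan(matrix(pmax(0, round(2000 + rnorm(n^2, 0, 20))), n, n))
  s2 <- roi_mean_pixel(noisy)
  expect_lt(abs(s2$mean - 2000), 4 * 20 / n)
  expect_equal(s2$n, n^2)
  expect_error(roi_mean_pixel(scan, c(5, 4, 1, 2)), "patch")
  expect_error(roi_mean_pixel(scan, c(1, 2, 5, 20)), "inside")
})

test_that("ascii_grid dose planes round trip, including NA cells", {
  set.seed(13)
  vals <- matrix(runif(12 * 10, 0, 300), 12, 10)
  vals[1, 1] <- NA
  pl <- dose_plane(vals, spacing = c(2, 2.5), origin = c(-9, -13.75),
                   sdd = 56.8, label = "round trip")
  path <- withr::local_tempfile(fileext = ".txt")
  write_dose_grid(pl, path)
  back <- read_dose_grid(path)
  expect_equal(back$values, pl$values, tolerance = 1e-9)
  expect_equal(back$spacing, pl$spacing)
  expect_equal(back$origin, pl$origin)
  expect_equal(back$sdd, 56.8)
})

test_that("ascii_grid reader rejects truncated or malformed files", {
  pl <- dose_plane(matrix(1:20, 4, 5), spacing = 2)
  path <- withr::local_tempfile(fileext = ".txt")
  write_dose_grid(pl, path)
  lines <- readLines(path)
  writeLines(lines[1:(length(lines) - 1)], path)
  expect_error(read_dose_grid(path), "promises")
  writeLines(c("something else", "entirely"), path)
  expect_error(read_dose_grid(path), "not an rcfqa")
})

test_that("DICOM RT Dose slices read with DoseGridScaling applied", {
  # stored value 25000 at scaling 1e-4 is 2.5 Gy = 250 cGy
  pl <- dose_plane(matrix(250, 8, 9), spacing = c(2, 3), origin = c(-8, -7))
  path <- withr::local_tempfile(fileext = ".dcm")
  rcfqa:::write_dicom_rt_dose(pl, path, scaling = 1e-4)
  back <- read_dose_grid(path, format = "dicom_rt_dose")
  expect_equal(back$values, pl$values)
  expect_equal(back$spacing, pl$spacing)
  expect_equal(back$origin, pl$origin)
  # general round trip at the writer's quantization
  set.seed(14)
  pl2 <- dose_plane(matrix(runif(30, 0, 400), 5, 6), spacing = 2)
  rcfqa:::write_dicom_rt_dose(pl2, path, scaling = 1e-4)
  expect_equal(read_dose_grid(path, format = "dicom_rt_dose")$values,
               pl2$values, tolerance = 1e-3)
})

test_that("DICOM reader errors on missing scaling and non-DICOM input", {
  path <- withr::local_tempfile(fileext = ".dcm")
  writeBin(as.raw(1:200), path)
  expect_error(read_dose_grid(path, format = "dicom_rt_dose"), "DICM")
  # strip DoseGridScaling from a valid file
  pl <- dose_plane(matrix(100, 4, 4), spacing = 2)
  rcfqa:::write_dicom_rt_dose(pl, path)
  raw <- readBin(path, "raw", file.info(path)$size)
  tag <- as.raw(c(0x04, 0x30, 0x0e, 0x00))  # (3004,000E) little endian
  hit <- which(vapply(seq_len(length(raw) - 3L), function(i)
    all(raw[i:(i + 3L)] == tag), logical(1)))[1]
  len <- rcfqa:::.u16(raw[(hit + 6L):(hit + 7L)])
  writeBin(raw[-(hit:(hit + 7L + len))], path)
  expect_error(read_dose_grid(path, format = "dicom_rt_dose"),
               "DoseGridScaling")
})
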