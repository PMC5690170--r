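test_that("rational fit recovers known dose-response parameters exactly", {
  # inverse of pixel = p0 - A d/(d + d0) is dose = a + b/(pixel - c)
  a <- -400; b <- 1.2e6; c <- 500
  mu <- c(50, 100, 200, 400, 600)
  dose <- 0.845 * mu
  pv <- c + b / (dose - a)
  pts <- data.frame(mu = mu, pixel_value = pv, dose = dose)
  cc <- build_calibration(pts, model = "rational")
  expect_equal(cc$params$a, a, tolerance = 1e-6)
  expect_equal(cc$params$b, b, tolerance = 1e-6)
  expect_equal(cc$params$c, c, tolerance = 1e-6)
  expect_lt(max(abs(cc$residuals)), 1e-6)
})

test_that("monotone spline reproduces every calibration point", {
  pts <- synthetic_calibration(seed = 20)
  cc <- build_calibration(pts, model = "monotone_spline")
  expect_equal(predict(cc, pts$pixel_value), pts$dose, tolerance = 1e-10)
  # strict monotonicity over the domain on a dense grid
  g <- seq(cc$domain[1], cc$domain[2], length.out = 1000)
  expect_true(all(diff(predict(cc, g)) < 0) || all(diff(predict(cc, g)) > 0))
})

test_that("non-monotone calibration points are refused with the offending pair", {
  pts <- data.frame(mu = c(50, 100, 200), pixel_value = c(3000, 2500, 2500),
                    dose = c(50, 100, 200))
  expect_error(build_calibration(pts), "not strictly monotone")
  pts2 <- data.frame(mu = c(50, 100, 200), pixel_value = c(3000, 3200, 2500),
                     dose = c(50, 100, 200))
  expect_error(build_calibration(pts2), "not strictly monotone")
  expect_error(build_calibration(pts[1:2, ]), ">= 3")
})

test_that("applying the calibration maps anchor pixel values to anchor doses", {
  cc <- exact_curve()
  pts <- synthetic_calibration(noise_sigma = 0, seed = 1)
  # a film whose every pixel equals the 200 MU patch value
  pv200 <- round(pts$pixel_value[pts$mu == 200])
  scan <- film_scan(matrix(pv200, 15, 15))
  plane <- apply_calibration(scan, cc)
  expect_equal(plane$values,
               matrix(predict(cc, pv200), 15, 15), tolerance = 1e-12)
  expect_equal(mean(plane$values), pts$dose[pts$mu == 200], tolerance = 0.01)
  expect_equal(plane$sdd, 56.8)
  expect_equal(plane$spacing, rep(25.4 / 75, 2))
  # all-unexposed film reads ~0 cGy
  un <- film_scan(matrix(attr(pts, "unexposed_pixel_value"), 10, 10))
  expect_lt(max(apply_calibration(un, cc)$values), 0.5)
})

test_that("noiseless simulated scans invert to the source plane within quantization", {
  cc <- exact_curve()
  tps <- make_square_field(10, dose = 169)
  scan <- simulate_film_scan(tps, noise_sigma = 0, seed = 1)
  film <- apply_calibration(scan, cc)
  film <- project_to_isocenter(film, 100)
  # compare on the film grid against the true plane
  ax <- plane_axes(film)
  g <- expand.grid(x = ax$x, y = ax$y)
  truth <- matrix(plane_value_at(tps, g$x, g$y), nrow = length(ax$y),
                  byrow = TRUE)
  # 1 LSB propagated through the curve slope at its shallowest point
  f <- rcfqa:::curve_fun(cc)
  slope_bound <- max(abs(f(seq(cc$domain[1], cc$domain[2], length.out = 200) + 0.5) -
                         f(seq(cc$domain[1], cc$domain[2], length.out = 200) - 0.5)))
  expect_lt(max(abs(film$values - truth)), slope_bound)
  # and well within 0.1% of the maximum dose
  expect_lt(max(abs(film$values - truth)) / max(truth), 0.004)
})

test_that("out-of-domain pixels follow the one-sided clamp policy", {
  cc <- exact_curve()
  lo_dose_edge <- max(cc$domain)  # darkening film: high pixel = low dose
  hi_dose_edge <- min(cc$domain)
  # background-side excursions clamp freely, whatever their number
  scan_bg <- film_scan(matrix(lo_dose_edge + 50, 10, 10))
  pl <- apply_calibration(scan_bg, cc)
  expect_lt(max(pl$values), 0.5)  # zero-dose anchor within fit tolerance
  expect_match(paste(attr(pl, "steps"), collapse = "; "), "background")
  # high-dose-side excursions: > 1% of pixels is an error
  px <- matrix(lo_dose_edge - 100, 10, 10)
  px[1:3, 1] <- hi_dose_edge - 10
  expect_error(apply_calibration(film_scan(px), cc), "inconsistent")
  # a single clamped pixel (1%) is tolerated and logged
  px2 <- matrix(lo_dose_edge - 100, 10, 10)
  px2[1, 1] <- hi_dose_edge - 10
  pl2 <- apply_calibration(film_scan(px2), cc)
  expect_match(paste(attr(pl2, "steps"), collapse = "; "), "high-dose")
  expect_equal(pl2$values[1, 1], predict(cc, hi_dose_edge))
})

test_that("tray transmission cancels between calibration and measurement", {
  tps <- make_square_field(10, dose = 169)
  center <- sapply(c(0.88, 0.942, 1.0), function(tt) {
    pts <- synthetic_calibration(noise_sigma = 0, tray_transmission = tt,
                                 seed = 1)
    cc <- build_calibration(pts,
                            unexposed_pixel_value = attr(pts, "unexposed_pixel_value"))
    scan <- simulate_film_scan(tps, noise_sigma = 0, tray_transmission = tt,
                               seed = 1)
    extract_point_dose(project_to_isocenter(apply_calibration(scan, cc), 100),
                       c(0, 0), 2)
  })
  expect_lt(max(center) - min(center), 0.3)  # quantization-level only
  expect_equal(mean(center), 169, tolerance = 0.005)
})

test_that("calibration curves survive a JSON round trip", {
  pts <- synthetic_calibration(seed = 21)
  cc <- build_calibration(pts,
                          unexposed_pixel_value = attr(pts, "unexposed_pixel_value"))
  path <- withr::local_tempfile(fileext = ".json")
  write_calibration(cc, path)
  back <- read_calibration(path)
  g <- seq(cc$domain[1], cc$domain[2], length.out = 100)
  expect_equal(predict(back, g), predict(cc, g), tolerance = 1e-6)
  expect_equal(back$model, cc$model)
  expect_error(read_calibration("no/such.json"), "not found")
})

test_that("calibration inversion is the right inverse of prediction", {
  cc <- default_curve()
  doses <- seq(5, 500, by = 7)
  pv <- calibration_inverse(cc, doses)
  expect_equal(predict(cc, pv), doses, tolerance = 1e-8)
  ccs <- build_calibration(synthetic_calibration(seed = 22),
                           model = "monotone_spline")
  doses2 <- seq(50, 450, by = 11)
  expect_equal(predict(ccs, calibration_inverse(ccs, doses2)), doses2,
               tolerance = 1e-3)
})

test_that("net optical density model fits and stays monotone", {
  pts <- synthetic_calibration(noise_sigma = 0, seed = 1)
  cc <- build_calibration(pts, model = "netod_poly",
                          unexposed_pixel_value = attr(pts, "unexposed_pixel_value"))
  expect_lt(max(abs(cc$residuals)) / max(pts$dose), 0.05)
  expect_error(build_calibration(pts, model = "netod_poly"), "unexposed")
})
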