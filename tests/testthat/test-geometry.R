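test_that("divergence projection scales geometry and preserves dose", {
  pl <- make_square_field(10, dose = 200, spacing = 1, sdd = 56.8,
                          extent = 12)
  # at 56.8 cm a 10 cm isocenter field spans +/- 2.84 cm
  p56 <- project_to_isocenter(make_square_field(10, dose = 200, sdd = 100),
                              56.8)
  w56 <- field_width_50(p56)
  expect_equal(w56, 56.8, tolerance = 1)   # mm: 5.68 cm full width
  p100 <- project_to_isocenter(p56, 100)
  expect_equal(field_width_50(p100), 100, tolerance = 1)
  # identity when target equals source
  same <- project_to_isocenter(p56, 56.8)
  expect_identical(same$values, p56$values)
  expect_equal(same$spacing, p56$spacing)
  # spacing scales by exactly the SDD ratio: 0.3387 mm -> 0.5963 mm
  sc <- dose_plane(matrix(1, 3, 3), spacing = 25.4 / 75, sdd = 56.8)
  expect_equal(project_to_isocenter(sc, 100)$spacing,
               rep(25.4 / 75 * 100 / 56.8, 2), tolerance = 1e-12)
  expect_equal(project_to_isocenter(sc, 100)$spacing[1], 0.5963,
               tolerance = 1e-4)
  expect_error(project_to_isocenter(sc, -1), "target_sdd")
})

test_that("field width scales by exactly the SDD ratio on synthetic squares", {
  for (size in c(5, 10, 15)) {
    at100 <- make_square_field(size, spacing = 0.5)
    at56 <- project_to_isocenter(at100, 56.8)
    expect_equal(field_width_50(at56) * (100 / 56.8),
                 field_width_50(resample_linear(at100, 0.5 * 100 / 56.8)),
                 tolerance = 0.02)
    expect_equal(plane_value_at(at56, 0, 0), plane_value_at(at100, 0, 0))
  }
})

test_that("gaussian smoothing is exact on constants and identity at sigma 0", {
  pl <- dose_plane(matrix(150, 20, 20), spacing = 1)
  sm <- gaussian_smooth(pl, 2)
  expect_equal(sm$values, pl$values, tolerance = 1e-12)
  set.seed(30)
  pl2 <- dose_plane(matrix(runif(400, 0, 100), 20, 20), spacing = 1)
  expect_identical(gaussian_smooth(pl2, 0)$values, pl2$values)
  expect_error(gaussian_smooth(pl2, -1), "sigma")
})

test_that("smoothing attenuates white noise by the kernel L2 norm", {
  spacing <- 0.5; sigma <- 1
  r <- ceiling(4 * sigma / spacing)
  k <- dnorm(-r:r, sd = sigma / spacing); k <- k / sum(k)
  l2_2d <- sqrt(sum(outer(k, k)^2))
  set.seed(31)
  n <- 400
  noise <- matrix(rnorm(n * n, 0, 5), n, n)
  pl <- dose_plane(100 + noise, spacing = spacing)
  sm <- gaussian_smooth(pl, sigma)
  core <- sm$values[50:(n - 50), 50:(n - 50)]
  expect_equal(sd(as.numeric(core)) / 5, l2_2d, tolerance = 0.03)
})

test_that("smoothing excludes NA cells and renormalizes around them", {
  v <- matrix(100, 15, 15); v[8, 8] <- NA
  sm <- gaussian_smooth(dose_plane(v, spacing = 1), 1)
  expect_true(is.na(sm$values[8, 8]))
  expect_equal(sm$values[-8, -8], matrix(100, 14, 14), tolerance = 1e-9)
})

test_that("linear resampling quadruples 2 mm grids to 0.5 mm and is exact on ramps", {
  pl <- ramp_plane(n = 21, spacing = 2)
  out <- resample_linear(pl, 0.5)
  expect_equal(dim(out$values), c(81L, 81L))  # 4N - 3 nodes from N
  ax <- plane_axes(out)
  g <- expand.grid(x = ax$x, y = ax$y)
  expect_equal(as.vector(t(out$values)), 100 + 2 * g$x + 1 * g$y,
               tolerance = 1e-12)
  # identity spacing keeps the grid
  same <- resample_linear(pl, 2)
  expect_equal(same$values, pl$values, tolerance = 1e-12)
  expect_error(resample_linear(pl, 0.001), "size cap")
})

test_that("coregistration recovers known translations to sub-grid precision", {
  base <- make_square_field(8, spacing = 1, extent = 14)
  expect_equal(coregister(base, base)$shift, c(0, 0), tolerance = 0.05)
  shifted <- dose_plane(base$values, spacing = base$spacing,
                        origin = base$origin + c(2.0, -1.5), sdd = base$sdd)
  t <- coregister(base, shifted)
  expect_equal(t$shift, c(2.0, -1.5), tolerance = 0.25)
  # applying the recovered transform realigns the plane
  aligned <- apply_transform(shifted, t, target = base)
  core <- !is.na(aligned$values)
  expect_lt(max(abs(aligned$values[core] - base$values[core])), 2)
})

test_that("coregistration flags featureless planes and refuses bad windows", {
  flat <- dose_plane(matrix(100, 21, 21), spacing = 2)
  expect_warning(t <- coregister(flat, flat), "featureless")
  expect_equal(t$shift, c(0, 0))
  expect_true(isTRUE(attr(t, "low_confidence")))
  base <- make_square_field(8, spacing = 1, extent = 14)
  big <- dose_plane(base$values, spacing = base$spacing,
                    origin = base$origin + c(9, 0), sdd = base$sdd)
  expect_error(coregister(base, big, search = 4), "window")
  moved_away <- dose_plane(base$values, spacing = base$spacing,
                           origin = base$origin + c(500, 0), sdd = base$sdd)
  expect_error(coregister(base, moved_away), "overlap")
  expect_equal(coregister(base, base, manual_shift = c(1.25, -0.5))$shift,
               c(1.25, -0.5))
})

test_that("apply_transform transports values exactly for identity and grid shifts", {
  set.seed(32)
  pl <- dose_plane(matrix(runif(225, 0, 200), 15, 15), spacing = 2)
  idt <- apply_transform(pl, registration_transform())
  expect_identical(idt$values, pl$values)
  # pure integer-grid shift: exact transport in the overlap
  sh <- apply_transform(pl, registration_transform(shift = c(4, -2)))
  expect_equal(sh$values[2:15, 1:13], pl$values[1:14, 3:15], tolerance = 1e-12)
  expect_true(all(is.na(sh$values[, 14:15])))
  # shift then inverse shift on a smooth plane: round trip
  sm <- make_square_field(8, spacing = 1, extent = 14)
  t <- registration_transform(shift = c(1.3, -0.7))
  round_trip <- apply_transform(apply_transform(sm, t), invert_transform(t))
  core <- !is.na(round_trip$values)
  # twice-interpolated penumbra: within ~1% of the field dose
  expect_lt(max(abs(round_trip$values[core] - sm$values[core])), 2)
})
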