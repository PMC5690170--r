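# Fixtures are built in code at test time; nothing binary ships with the
# package.

# affine dose surface D(x, y) = a + bx*x + by*y (kept non-negative)
ramp_plane <- function(n = 11, spacing = 2, a = 100, bx = 2, by = 1,
                       sdd = 100) {
  half <- (n - 1) / 2 * spacing
  ax <- seq(-half, half, by = spacing)
  vals <- outer(ax, ax, function(y, x) a + bx * x + by * y)
  stopifnot(all(vals >= 0))
  dose_plane(vals, spacing = spacing, origin = c(-half, -half), sdd = sdd)
}

# smooth structured plane plus seeded noise, for gamma map-vs-oracle sweeps
noisy_pair <- function(seed, n = 12, spacing = 2, noise = 4) {
  set.seed(seed)
  base <- 100 + 60 * sin(outer(seq_len(n), seq_len(n),
                               function(i, j) 0.31 * i + 0.23 * j + seed))
  base <- pmax(base, 0)
  half <- (n - 1) / 2 * spacing
  ref <- dose_plane(base, spacing = spacing, origin = c(-half, -half))
  ev <- dose_plane(pmax(base + matrix(stats::rnorm(n * n, 0, noise), n, n), 0),
                   spacing = spacing, origin = c(-half, -half))
  list(ref = ref, ev = ev)
}

# full width at half maximum of the central horizontal profile (mm)
field_width_50 <- function(plane) {
  ax <- plane_axes(plane)
  prof <- plane_value_at(plane, ax$x, rep(0, length(ax$x)))
  half <- max(prof) / 2
  above <- which(prof >= half)
  l <- above[1]; r <- above[length(above)]
  xl <- if (l > 1)
    stats::approx(prof[c(l - 1, l)], ax$x[c(l - 1, l)], xout = half)$y
  else ax$x[l]
  xr <- if (r < length(prof))
    stats::approx(prof[c(r, r + 1)], ax$x[c(r, r + 1)], xout = half)$y
  else ax$x[r]
  xr - xl
}

# calibration curve fitted from a noiseless synthetic session (exact anchor)
exact_curve <- function() {
  pts <- synthetic_calibration(noise_sigma = 0, seed = 1)
  build_calibration(pts,
                    unexposed_pixel_value = attr(pts, "unexposed_pixel_value"))
}

default_curve <- function(seed = 101) {
  pts <- synthetic_calibration(seed = seed)
  build_calibration(pts,
                    unexposed_pixel_value = attr(pts, "unexposed_pixel_value"))
}
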