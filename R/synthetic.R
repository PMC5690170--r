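# Synthetic study conditions: matched TPS planes and film scans emulating
# the tray-transmission geometry (film at SDD 56.8 cm, TPS plane at 100 cm,
# tray transmission 0.942, 75 dpi / 12-bit scans), including deliveries with
# injected errors.  All randomness is drawn through an explicit seed; the
# same seed reproduces the same scan bit for bit.

with_seed_local <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Synthetic square field
#'
#' An open square field with error-function edges: `D(x, y) = dose * S(x) *
#' S(y)` with `S(u) = pnorm((size/2 - u)/sigma) + pnorm((size/2 + u)/sigma)
#' - 1`, so the 50% isodose falls at +/- size/2 and `penumbra_sigma -> 0`
#' gives an ideal step field.
#'
#' @param size field side at the plane's SDD, in cm.
#' @param dose central-axis dose in cGy (default 200, i.e. a 200 MU-class
#'   delivery).
#' @param penumbra_sigma edge width parameter in mm (default 3).
#' @param spacing grid step in mm (default 2).
#' @param extent full grid side in cm (default `1.6 * size`, at least
#'   size + 6 cm).
#' @param sdd SDD of the plane in cm (default 100).
#' @return a `dose_plane`.
#' @export
make_square_field <- function(size, dose = 200, penumbra_sigma = 3,
                              spacing = 2, extent = NULL, sdd = 100) {
  if (!is.finite(size) || size <= 0) stop("'size' must be > 0 (cm)")
  if (!is.finite(dose) || dose <= 0) stop("'dose' must be > 0 (cGy)")
  if (!is.finite(penumbra_sigma) || penumbra_sigma < 0)
    stop("'penumbra_sigma' must be >= 0 (mm)")
  if (is.null(extent)) extent <- max(1.6 * size, size + 6)
  if (extent < size)
    stop(sprintf("field of %g cm exceeds the %g cm grid extent", size, extent))
  half_mm <- extent * 10 / 2
  n <- floor(half_mm / spacing)
  ax <- (-n:n) * spacing
  s <- edge_profile(ax, -size * 10 / 2, size * 10 / 2, penumbra_sigma)
  vals <- dose * outer(s, s)
  dose_plane(vals, spacing = spacing, origin = c(ax[1], ax[1]), sdd = sdd,
             label = sprintf("square field %g cm", size))
}

# soft-edged indicator of [a, b]; sigma = 0 gives the sharp indicator
edge_profile <- function(u, a, b, sigma) {
  if (sigma == 0) return(as.numeric(u >= a & u <= b))
  stats::pnorm((b - u) / sigma) + stats::pnorm((u - a) / sigma) - 1
}

#' Synthetic modulated (IMRT-like) plane
#'
#' Weighted superposition of soft-edged rectangular segments:
#' `D = dose_scale * sum_i w_i * E(x; x1_i, x2_i) * E(y; y1_i, y2_i)` with
#' the same error-function edge model as [make_square_field()].  One
#' centered segment reduces exactly to a square field.
#'
#' @param segments list of segments, each `list(rect = c(x1, x2, y1, y2))`
#'   in mm at the plane's SDD and `weight` in cGy.
#' @param dose_scale overall multiplier (default 1); scaling it emulates a
#'   uniform monitor-unit error.
#' @param penumbra_sigma edge width in mm (default 3).
#' @param spacing grid step in mm (default 2).
#' @param extent full grid side in cm (default 16).
#' @param sdd SDD in cm (default 100).
#' @return a `dose_plane`.
#' @export
make_imrt_plane <- function(segments, dose_scale = 1, penumbra_sigma = 3,
                            spacing = 2, extent = 16, sdd = 100) {
  if (length(segments) == 0L) stop("'segments' must not be empty")
  if (!is.finite(dose_scale) || dose_scale < 0) stop("'dose_scale' must be >= 0")
  half_mm <- extent * 10 / 2
  n <- floor(half_mm / spacing)
  ax <- (-n:n) * spacing
  vals <- matrix(0, length(ax), length(ax))
  for (seg in segments) {
    r <- seg$rect
    if (length(r) != 4L || r[1] >= r[2] || r[3] >= r[4])
      stop("each segment needs rect = c(x1, x2, y1, y2) with x1 < x2, y1 < y2")
    vals <- vals + seg$weight *
      outer(edge_profile(ax, r[3], r[4], penumbra_sigma),
            edge_profile(ax, r[1], r[2], penumbra_sigma))
  }
  dose_plane(dose_scale * vals, spacing = spacing, origin = c(ax[1], ax[1]),
             sdd = sdd, label = "modulated plane")
}

#' Five example modulated plans
#'
#' Fixed segment lists for five IMRT-like plans with central-axis doses in
#' the 180-260 cGy range typical of a single QA delivery.  Every plan has a
#' dominant segment covering the central axis, so removing a field both
#' distorts the distribution and shifts the normalization-point dose, as a
#' genuinely dropped field would.
#'
#' @return a named list of five segment lists for [make_imrt_plane()].
#' @export
imrt_example_plans <- function() {
  list(
    plan1 = list(
      list(rect = c(-50, 50, -50, 50), weight = 130),
      list(rect = c(-50, 0, -30, 30), weight = 55),
      list(rect = c(-20, 45, -45, -5), weight = 40),
      list(rect = c(-10, 30, 5, 50), weight = 25)),
    plan2 = list(
      list(rect = c(-40, 40, -55, 55), weight = 95),
      list(rect = c(-40, 10, -20, 40), weight = 45),
      list(rect = c(5, 40, -50, 10), weight = 35),
      list(rect = c(-35, -5, -50, -15), weight = 20)),
    plan3 = list(
      list(rect = c(-55, 55, -40, 40), weight = 140),
      list(rect = c(-25, 25, -25, 25), weight = 60),
      list(rect = c(-55, -10, -15, 35), weight = 30),
      list(rect = c(15, 50, -35, 20), weight = 25)),
    plan4 = list(
      list(rect = c(-45, 45, -45, 45), weight = 120),
      list(rect = c(-15, 45, -15, 40), weight = 50),
      list(rect = c(-45, 5, -40, 0), weight = 35),
      list(rect = c(-30, 25, 10, 45), weight = 25)),
    plan5 = list(
      list(rect = c(-50, 40, -40, 50), weight = 110),
      list(rect = c(-20, 40, -40, 15), weight = 45),
      list(rect = c(-50, 10, -10, 45), weight = 30),
      list(rect = c(-45, -5, -40, 5), weight = 20)))
}

#' Synthetic film dose-response characteristic
#'
#' The intrinsic darkening curve of the synthetic film: pixel value
#' `p(D) = p0 - A * D / (D + D_half)`, strictly decreasing in dose (a
#' digitizer that reads darker film as lower pixel values).  Its inverse is
#' exactly of the rational form `dose = a + b / (pixel - c)` the default
#' calibration model fits.
#'
#' @param p0 unexposed-film pixel value (default 3500 on the 12-bit scale).
#' @param amplitude total pixel-value swing (default 3000).
#' @param d_half dose of half response in cGy (default 400).
#' @return a function mapping dose (cGy) to (continuous) pixel value, with
#'   attribute `params`.
#' @export
synthetic_response <- function(p0 = 3500, amplitude = 3000, d_half = 400) {
  f <- function(dose) p0 - amplitude * dose / (dose + d_half)
  attr(f, "params") <- list(p0 = p0, amplitude = amplitude, d_half = d_half)
  f
}

#' Simulate the tray calibration irradiations
#'
#' Emulates the calibration session: uniform film patches irradiated on the
#' tray (SDD 56.8 cm) at the standard monitor-unit levels, scanned, and
#' paired with the TPS dose at the phantom center at 100 cm for the same
#' MU.  The tray transmission enters the simulated pixel values exactly as
#' it does the QA scans, so it cancels through the fitted calibration.
#'
#' @param mu monitor-unit levels (default `c(50, 100, 200, 400, 600)`).
#' @param dose_per_mu TPS dose per MU at the phantom center, cGy/MU
#'   (default 0.845, a 6 MV 10 cm x 10 cm output at the reference depth).
#' @param response film characteristic from [synthetic_response()].
#' @param tray_transmission tray attenuation applied to the film dose
#'   (default 0.942).
#' @param noise_sigma pixel-noise standard deviation (default 1% of the
#'   12-bit range).
#' @param patch_px side of the simulated uniform patch in pixels
#'   (default 40).
#' @param bit_depth scanner bit depth (default 12).
#' @param seed RNG seed (`NULL` = use current RNG state).
#' @return a data frame with columns `mu`, `pixel_value`, `dose` plus
#'   attribute `unexposed_pixel_value`.
#' @export
synthetic_calibration <- function(mu = c(50, 100, 200, 400, 600),
                                  dose_per_mu = 0.845,
                                  response = synthetic_response(),
                                  tray_transmission = 0.942,
                                  noise_sigma = 0.01 * 4096,
                                  patch_px = 40, bit_depth = 12,
                                  seed = NULL) {
  with_seed_local(seed, {
    vmax <- 2^bit_depth - 1
    pv <- vapply(mu, function(m) {
      dose_film <- m * dose_per_mu * tray_transmission
      px <- response(dose_film) + stats::rnorm(patch_px^2, sd = noise_sigma)
      mean(pmin(pmax(round(px), 0), vmax))
    }, numeric(1))
    out <- data.frame(mu = mu, pixel_value = pv, dose = mu * dose_per_mu)
    attr(out, "unexposed_pixel_value") <-
      min(max(round(response(0)), 0), vmax)
    out
  })
}

#' Simulate a film scan of a planned dose distribution
#'
#' Fabricates the scan a tray film of the given isocenter-plane dose
#' distribution would produce: the plane is demagnified along the beam
#' divergence to the film SDD, optionally misaligned (film placement
#' error), attenuated by the tray, mapped through the film characteristic,
#' degraded with Gaussian pixel noise, and quantized to the scanner bit
#' depth.  Identical seeds give bit-identical scans.
#'
#' @param plane_at_iso a `dose_plane` at SDD 100 cm.
#' @param response film characteristic (dose -> pixel value), e.g.
#'   [synthetic_response()].
#' @param dpi scanner resolution (default 75).
#' @param bit_depth scanner bit depth (default 12).
#' @param noise_sigma pixel-noise SD (default 1% of the 12-bit range).
#' @param misalignment a `registration_transform` displacing the film
#'   relative to its nominal position (mm at the film plane; default none).
#' @param tray_transmission tray attenuation (default 0.942).
#' @param film_sdd film SDD in cm (default 56.8).
#' @param seed RNG seed (`NULL` = use current RNG state).
#' @return a `film_scan`.
#' @export
simulate_film_scan <- function(plane_at_iso, response = synthetic_response(),
                               dpi = 75, bit_depth = 12,
                               noise_sigma = 0.01 * 4096,
                               misalignment = registration_transform(),
                               tray_transmission = 0.942,
                               film_sdd = 56.8, seed = NULL) {
  stopifnot(inherits(plane_at_iso, "dose_plane"),
            inherits(misalignment, "registration_transform"))
  demag <- project_to_isocenter(plane_at_iso, film_sdd)
  sp <- 25.4 / dpi
  ext <- plane_extent(demag)
  half <- min(abs(unlist(ext)))
  n <- floor(half / sp)
  ax <- (-n:n) * sp
  target <- dose_plane(matrix(0, length(ax), length(ax)), spacing = sp,
                       origin = c(ax[1], ax[1]), sdd = film_sdd)
  # film displaced by +shift: sample the plan at p - shift
  t_inv <- registration_transform(shift = -misalignment$shift,
                                  scale = 1 / misalignment$scale,
                                  rotation = -misalignment$rotation)
  dosed <- apply_transform(demag, t_inv, target = target)
  d <- dosed$values
  d[is.na(d)] <- 0  # beyond the plan grid the film is unirradiated
  px_true <- response(d * tray_transmission)
  vmax <- 2^bit_depth - 1
  with_seed_local(seed, {
    px <- px_true + stats::rnorm(length(px_true), sd = noise_sigma)
    px <- matrix(pmin(pmax(round(px), 0), vmax), nrow = nrow(px_true))
    film_scan(px, bit_depth = bit_depth, dpi = dpi, sdd = film_sdd,
              steps = sprintf("simulate_film_scan: noise %.3g px, shift (%.3g, %.3g) mm, tray %.3f",
                              noise_sigma, misalignment$shift[1],
                              misalignment$shift[2], tray_transmission))
  })
}

#' Build the error-injection scenario set
#'
#' For each of the five example plans, five delivery scenarios mirroring a
#' commissioning campaign: (1) faithful delivery; (2) a repeat faithful
#' delivery with fresh noise (a second session); (3) faithful delivery with
#' a small random film misalignment (surrogate for delivering at the real
#' gantry angles); (4) a uniform monitor-unit deficit of 10-37%; (5) one
#' field removed.  Scenarios 1-3 are expected to Pass, 4-5 to Fail.
#'
#' @param plans named list of segment lists (default
#'   [imrt_example_plans()]).
#' @param seed base seed; per-scenario seeds and injected error magnitudes
#'   derive from it deterministically.
#' @return a data frame (one row per scenario) with the plan name, variant,
#'   injected `dose_scale`, `removed_segment`, misalignment components,
#'   per-scenario `scan_seed` and the `expected` verdict.
#' @export
make_error_scenarios <- function(plans = imrt_example_plans(), seed = 1) {
  stopifnot(length(plans) >= 1L)
  with_seed_local(seed, {
    rows <- list()
    for (p in seq_along(plans)) {
      deficit <- stats::runif(1, 0.10, 0.37)
      mis <- stats::runif(2, -0.7, 0.7)
      heaviest <- which.max(vapply(plans[[p]], `[[`, numeric(1), "weight"))
      variants <- list(
        list(variant = "faithful", dose_scale = 1, removed = NA_integer_,
             mis = c(0, 0), expected = "Pass"),
        list(variant = "repeat", dose_scale = 1, removed = NA_integer_,
             mis = c(0, 0), expected = "Pass"),
        list(variant = "misaligned", dose_scale = 1, removed = NA_integer_,
             mis = mis, expected = "Pass"),
        list(variant = "lower_mu", dose_scale = 1 - deficit,
             removed = NA_integer_, mis = c(0, 0), expected = "Fail"),
        list(variant = "field_removed", dose_scale = 1, removed = heaviest,
             mis = c(0, 0), expected = "Fail"))
      for (v in seq_along(variants)) {
        vv <- variants[[v]]
        rows[[length(rows) + 1L]] <- data.frame(
          plan = names(plans)[p], variant = vv$variant,
          dose_scale = vv$dose_scale, removed_segment = vv$removed,
          mis_x = vv$mis[1], mis_y = vv$mis[2],
          scan_seed = (seed %% 100000L) * 1000L + p * 10L + v,
          expected = vv$expected)
      }
    }
    do.call(rbind, rows)
  })
}

#' Run one synthetic scenario through the full QA pipeline
#'
#' Builds the TPS plane and the (possibly corrupted) delivered plane for a
#' scenario row, simulates the film scan, fits the calibration from its own
#' simulated session, and analyzes the pair with [qa_analyze()].
#'
#' @param scenario one row of [make_error_scenarios()].
#' @param plans the plan list the scenarios refer to.
#' @param curve optional pre-built `calibration_curve`; by default a
#'   calibration session is simulated (seeded from the scenario) and
#'   fitted.
#' @param policy a [qa_policy()].
#' @param target_spacing comparison-grid spacing in mm (default 1).
#' @param ... further arguments to [qa_analyze()].
#' @return a `qa_result` with attribute `scenario`.
#' @export
run_qa_scenario <- function(scenario, plans = imrt_example_plans(),
                            curve = NULL, policy = qa_policy(),
                            target_spacing = 1, ...) {
  stopifnot(is.data.frame(scenario), nrow(scenario) == 1L)
  segs <- plans[[scenario$plan]]
  tps <- make_imrt_plane(segs)
  delivered_segs <- segs
  if (!is.na(scenario$removed_segment))
    delivered_segs <- segs[-scenario$removed_segment]
  delivered <- make_imrt_plane(delivered_segs,
                               dose_scale = scenario$dose_scale)
  if (is.null(curve)) {
    pts <- synthetic_calibration(seed = scenario$scan_seed + 500000L)
    curve <- build_calibration(
      pts, unexposed_pixel_value = attr(pts, "unexposed_pixel_value"))
  }
  scan <- simulate_film_scan(
    delivered,
    misalignment = registration_transform(shift = c(scenario$mis_x,
                                                    scenario$mis_y)),
    seed = scenario$scan_seed)
  res <- qa_analyze(scan, tps, curve, policy = policy,
                    target_spacing = target_spacing, ...)
  attr(res, "scenario") <- scenario
  res
}
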