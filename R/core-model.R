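#' rcfqa: transmission QA for radiotherapy with radiochromic film
#'
#' In-vivo transmission quality assurance compares the 2D dose distribution
#' measured by a radiochromic film mounted on a tray in the linac accessory
#' holder (source-to-detector distance 56.8 cm) with the dose plane the
#' treatment planning system (TPS) calculates on the coronal central plane of
#' a phantom at 100 cm.  The package covers the whole chain: reading film
#' scans and dose grids, pixel-to-dose calibration anchored to TPS doses,
#' beam-divergence projection to the isocenter plane, denoising, resampling,
#' profile-based coregistration, gamma analysis, and the Pass/Fail verdict.
#'
#' Coordinate convention: physical coordinates in mm with the origin at the
#' projection of the beam central axis, x = crossplane (grid columns),
#' y = inplane (grid rows).  Grids are stored as matrices with `values[i, j]`
#' at physical position `(origin[1] + (j-1)*spacing[1],
#' origin[2] + (i-1)*spacing[2])`.  Doses are in cGy throughout.
#'
#' @useDynLib rcfqa, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @keywords internal
"_PACKAGE"

#' Construct a 2D dose plane
#'
#' A `dose_plane` is an absolute 2D dose grid with physical spacing, an
#' origin relative to the beam central axis, and the source-to-detector
#' distance (SDD) at which it lives.  Dose values are in cGy.  `NA` cells
#' mark regions with no information (e.g. outside the film after
#' registration); they are excluded from downstream comparisons.
#'
#' @param values numeric matrix of doses (cGy); rows = inplane (y),
#'   columns = crossplane (x).  Non-`NA` values must be >= 0.
#' @param spacing grid step in mm; scalar or `c(dx, dy)`.
#' @param origin physical coordinate (mm) of `values[1, 1]` relative to the
#'   beam central axis; `c(x0, y0)`.
#' @param sdd source-to-detector distance in cm (must be > 0).
#' @param label free-text description.
#' @return an object of class `dose_plane`.
#' @examples
#' pl <- dose_plane(matrix(200, 11, 11), spacing = 2, origin = c(-10, -10))
#' plane_value_at(pl, 0, 0)
#' @export
dose_plane <- function(values, spacing, origin = NULL, sdd = 100, label = "") {
  values <- as.matrix(values)
  if (!is.numeric(values) || length(values) == 0L)
    stop("'values' must be a non-empty numeric matrix")
  if (any(values < 0, na.rm = TRUE))
    stop("dose values must be >= 0 (cGy)")
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- c(spacing, spacing)
  if (length(spacing) != 2L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be one or two positive numbers (mm)")
  if (is.null(origin)) {
    # default: grid centered on the central axis
    origin <- -spacing * (rev(dim(values)) - 1) / 2
  }
  origin <- as.numeric(origin)
  if (length(origin) != 2L || any(!is.finite(origin)))
    stop("'origin' must be two finite numbers (mm)")
  if (!is.numeric(sdd) || length(sdd) != 1L || !is.finite(sdd) || sdd <= 0)
    stop("'sdd' must be a single positive number (cm)")
  structure(list(values = values, spacing = spacing, origin = origin,
                 sdd = as.numeric(sdd), label = as.character(label)),
            class = "dose_plane")
}

#' @export
print.dose_plane <- function(x, ...) {
  d <- dim(x$values)
  ext <- plane_extent(x)
  cat(sprintf("dose plane%s: %d x %d (rows x cols), spacing %.4g x %.4g mm, SDD %.1f cm\n",
              if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
              d[1], d[2], x$spacing[1], x$spacing[2], x$sdd))
  cat(sprintf("  extent x [%.1f, %.1f] mm, y [%.1f, %.1f] mm; dose range [%.2f, %.2f] cGy; %d NA\n",
              ext$x[1], ext$x[2], ext$y[1], ext$y[2],
              min(x$values, na.rm = TRUE), max(x$values, na.rm = TRUE),
              sum(is.na(x$values))))
  invisible(x)
}

#' Physical axes of a dose plane
#'
#' @param plane a `dose_plane`.
#' @return list with components `x` (column coordinates, mm) and `y` (row
#'   coordinates, mm).
#' @export
plane_axes <- function(plane) {
  stopifnot(inherits(plane, "dose_plane"))
  d <- dim(plane$values)
  list(x = plane$origin[1] + (seq_len(d[2]) - 1) * plane$spacing[1],
       y = plane$origin[2] + (seq_len(d[1]) - 1) * plane$spacing[2])
}

#' Physical extent of a dose plane
#'
#' @param plane a `dose_plane`.
#' @return list with `x` and `y` ranges in mm.
#' @export
plane_extent <- function(plane) {
  ax <- plane_axes(plane)
  list(x = range(ax$x), y = range(ax$y))
}

#' Bilinear dose lookup at physical coordinates
#'
#' Interpolates the plane bilinearly at arbitrary interior points.  Exact
#' grid nodes return the stored value; affine dose surfaces are reproduced
#' exactly.  Points outside the physical extent raise an error rather than
#' extrapolating.
#'
#' @param plane a `dose_plane`.
#' @param x,y physical coordinates in mm (vectors of equal length, recycled).
#' @return numeric vector of doses (cGy); `NA` where any of the four
#'   surrounding nodes is `NA`.
#' @export
plane_value_at <- function(plane, x, y) {
  stopifnot(inherits(plane, "dose_plane"))
  n <- max(length(x), length(y))
  x <- rep_len(as.numeric(x), n); y <- rep_len(as.numeric(y), n)
  ext <- plane_extent(plane)
  tol <- 1e-9 * max(1, abs(unlist(ext)))
  if (any(x < ext$x[1] - tol | x > ext$x[2] + tol |
          y < ext$y[1] - tol | y > ext$y[2] + tol, na.rm = TRUE))
    stop(sprintf("query point outside plane extent x[%.2f, %.2f], y[%.2f, %.2f] mm",
                 ext$x[1], ext$x[2], ext$y[1], ext$y[2]))
  x <- pmin(pmax(x, ext$x[1]), ext$x[2])
  y <- pmin(pmax(y, ext$y[1]), ext$y[2])
  ax <- plane_axes(plane)
  if (length(ax$x) == 1L && length(ax$y) == 1L) return(rep(plane$values[1, 1], n))
  if (length(ax$x) == 1L) return(stats::approx(ax$y, plane$values[, 1], xout = y)$y)
  if (length(ax$y) == 1L) return(stats::approx(ax$x, plane$values[1, ], xout = x)$y)
  bilinear_lookup(ax$x, ax$y, plane$values, x, y)
}

# vectorized bilinear interpolation on a rectilinear grid (rows = y)
bilinear_lookup <- function(gx, gy, V, x, y) {
  jx <- findInterval(x, gx, rightmost.closed = TRUE)
  jx[jx < 1L] <- 1L; jx[jx >= length(gx)] <- length(gx) - 1L
  iy <- findInterval(y, gy, rightmost.closed = TRUE)
  iy[iy < 1L] <- 1L; iy[iy >= length(gy)] <- length(gy) - 1L
  wx <- (x - gx[jx]) / (gx[jx + 1L] - gx[jx])
  wy <- (y - gy[iy]) / (gy[iy + 1L] - gy[iy])
  wx <- pmin(pmax(wx, 0), 1); wy <- pmin(pmax(wy, 0), 1)
  v11 <- V[cbind(iy, jx)];      v12 <- V[cbind(iy, jx + 1L)]
  v21 <- V[cbind(iy + 1L, jx)]; v22 <- V[cbind(iy + 1L, jx + 1L)]
  (1 - wy) * ((1 - wx) * v11 + wx * v12) + wy * ((1 - wx) * v21 + wx * v22)
}

#' In-plane registration transform
#'
#' A rigid similarity transform mapping reference-frame coordinates to
#' moving-frame coordinates: `p_mov = scale * R(rotation) p_ref + shift`.
#' `coregister()` estimates `shift` as the displacement of the moving plane
#' relative to the reference (a moving plane whose features sit at +d mm
#' relative to the reference yields `shift = d`).
#'
#' @param shift per-axis translation `c(dx, dy)` in mm.
#' @param scale unitless magnification (> 0).
#' @param rotation in-plane angle in degrees (default 0).
#' @return an object of class `registration_transform`.
#' @export
registration_transform <- function(shift = c(0, 0), scale = 1, rotation = 0) {
  shift <- as.numeric(shift)
  if (length(shift) != 2L || any(!is.finite(shift)))
    stop("'shift' must be two finite numbers (mm)")
  if (!is.finite(scale) || scale <= 0) stop("'scale' must be > 0")
  if (!is.finite(rotation)) stop("'rotation' must be finite (degrees)")
  structure(list(shift = shift, scale = as.numeric(scale),
                 rotation = as.numeric(rotation)),
            class = "registration_transform")
}

#' @export
print.registration_transform <- function(x, ...) {
  cat(sprintf("registration transform: shift (%.3f, %.3f) mm, scale %.6g, rotation %.3g deg\n",
              x$shift[1], x$shift[2], x$scale, x$rotation))
  invisible(x)
}

#' Apply a registration transform to coordinates
#'
#' Maps reference-frame points into the moving frame.
#'
#' @param t a `registration_transform`.
#' @param x,y coordinates in mm.
#' @return list with transformed `x` and `y`.
#' @export
transform_points <- function(t, x, y) {
  stopifnot(inherits(t, "registration_transform"))
  th <- t$rotation * pi / 180
  xr <- cos(th) * x - sin(th) * y
  yr <- sin(th) * x + cos(th) * y
  list(x = t$scale * xr + t$shift[1], y = t$scale * yr + t$shift[2])
}

#' Invert a registration transform
#'
#' @param t a `registration_transform`.
#' @return the inverse `registration_transform`; composing the two is the
#'   identity to numerical tolerance.
#' @export
invert_transform <- function(t) {
  stopifnot(inherits(t, "registration_transform"))
  th <- -t$rotation * pi / 180
  s <- -t$shift / t$scale
  registration_transform(
    shift = c(cos(th) * s[1] - sin(th) * s[2],
              sin(th) * s[1] + cos(th) * s[2]),
    scale = 1 / t$scale, rotation = -t$rotation)
}

#' Gamma-analysis criteria
#'
#' @param dose_tol dose-difference criterion as % of the normalization dose
#'   (default 3).
#' @param dta_tol distance-to-agreement criterion in mm (default 3).
#' @param threshold low-dose cutoff as a fraction of the normalization dose
#'   (default 0.10); reference points below it are not evaluated.
#' @param normalization `"global_max"` (normalization dose = maximum of the
#'   reference plane) or `"point_dose"` (dose of the reference plane at
#'   `norm_point`).
#' @param norm_point normalization-point coordinates in mm (used by
#'   `"point_dose"`); default the central axis `c(0, 0)`.
#' @param search_radius_factor multiple of `dta_tol` bounding the spatial
#'   search (default 3; gamma contributions beyond it exceed 3 and cannot
#'   change agreement status).
#' @return an object of class `gamma_criteria`.
#' @export
gamma_criteria <- function(dose_tol = 3, dta_tol = 3, threshold = 0.10,
                           normalization = c("global_max", "point_dose"),
                           norm_point = c(0, 0), search_radius_factor = 3) {
  normalization <- match.arg(normalization)
  if (!is.finite(dose_tol) || dose_tol <= 0) stop("'dose_tol' must be > 0 (%)")
  if (!is.finite(dta_tol) || dta_tol <= 0) stop("'dta_tol' must be > 0 (mm)")
  if (!is.finite(threshold) || threshold < 0 || threshold >= 1)
    stop("'threshold' must be in [0, 1)")
  if (!is.finite(search_radius_factor) || search_radius_factor <= 0)
    stop("'search_radius_factor' must be > 0")
  structure(list(dose_tol = dose_tol, dta_tol = dta_tol, threshold = threshold,
                 normalization = normalization, norm_point = as.numeric(norm_point),
                 search_radius_factor = search_radius_factor),
            class = "gamma_criteria")
}

#' @export
print.gamma_criteria <- function(x, ...) {
  cat(sprintf("gamma criteria: %g%% / %g mm, threshold %g%%, %s normalization\n",
              x$dose_tol, x$dta_tol, 100 * x$threshold, x$normalization))
  invisible(x)
}

#' QA acceptance policy
#'
#' The transmission QA verdict is Pass when, simultaneously, the absolute
#' percent dose difference at the normalization point is below
#' `max_point_diff` and the gamma pass rate exceeds `min_pass_rate`.  Both
#' inequalities are strict, so a point difference of exactly 5% or a pass
#' rate of exactly 95% fails.
#'
#' @param gamma a `gamma_criteria` object.
#' @param max_point_diff verdict bound on the absolute percent point-dose
#'   difference (default 5, strict).
#' @param min_pass_rate verdict bound on the gamma pass rate in % (default
#'   95, strict).
#' @param tray_transmission fraction of the beam transmitted through the film
#'   tray (default 0.942 for a 6 MV beam on the acrylic support).  It cancels
#'   between calibration and measurement, but matters for the dose actually
#'   delivered to the patient.
#' @return an object of class `qa_policy`.
#' @export
qa_policy <- function(gamma = gamma_criteria(), max_point_diff = 5,
                      min_pass_rate = 95, tray_transmission = 0.942) {
  stopifnot(inherits(gamma, "gamma_criteria"))
  if (!is.finite(max_point_diff) || max_point_diff <= 0)
    stop("'max_point_diff' must be > 0 (%)")
  if (!is.finite(min_pass_rate) || min_pass_rate <= 0 || min_pass_rate > 100)
    stop("'min_pass_rate' must be in (0, 100]")
  if (!is.finite(tray_transmission) || tray_transmission <= 0 || tray_transmission > 1)
    stop("'tray_transmission' must be in (0, 1]")
  structure(list(gamma = gamma, max_point_diff = max_point_diff,
                 min_pass_rate = min_pass_rate,
                 tray_transmission = tray_transmission),
            class = "qa_policy")
}

#' @export
print.qa_policy <- function(x, ...) {
  cat(sprintf("QA policy: |point diff| < %g%% and gamma pass rate > %g%% (both strict)\n",
              x$max_point_diff, x$min_pass_rate))
  print(x$gamma)
  cat(sprintf("  tray transmission %.3f\n", x$tray_transmission))
  invisible(x)
}
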