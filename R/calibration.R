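#' Build a pixel-value-to-dose calibration curve
#'
#' The calibration ties the response of film irradiated on the tray in the
#' accessory holder (SDD 56.8 cm) to the absorbed dose the TPS calculates at
#' the phantom center at SDD 100 cm for the same monitor units.  Because
#' calibration films and QA films share the tray geometry, the tray
#' transmission cancels and the fitted curve maps pixel values directly onto
#' the TPS (100 cm) dose scale.
#'
#' Three monotone models are available:
#' \describe{
#'   \item{`rational`}{`dose = a + b / (pixel - c)`, the standard
#'     radiochromic dose-response shape; default.  Fitted by
#'     Levenberg-Marquardt least squares with an exact three-point start.
#'     Fits whose pole `c` falls inside the pixel-value domain (hence a
#'     non-monotone model) are refused.}
#'   \item{`monotone_spline`}{Hyman-filtered monotone cubic interpolant
#'     through the points; assumption-free, residuals are zero by
#'     construction.}
#'   \item{`netod_poly`}{quadratic polynomial in net optical density
#'     `OD = log10(PV_unexposed / PV)`; requires `unexposed_pixel_value`.}
#' }
#'
#' @param points data frame with columns `mu`, `pixel_value`, `dose`
#'   (monitor units, ROI-mean pixel value, TPS dose in cGy); at least 3
#'   rows.  Pixel values must be strictly monotone in dose, in either
#'   direction (the digitizer polarity is not assumed).
#' @param model one of `"rational"`, `"monotone_spline"`, `"netod_poly"`.
#' @param unexposed_pixel_value pixel value of un-irradiated film; optional
#'   zero-dose anchor appended to the fit (required for `netod_poly`).
#' @return an object of class `calibration_curve` with the fitted model,
#'   per-point `residuals` (cGy), the pixel-value `domain` covered, and a
#'   `fit_tol` equal to the maximum absolute residual.
#' @examples
#' pts <- data.frame(mu = c(50, 100, 200, 400, 600),
#'                   pixel_value = c(3100, 2800, 2350, 1800, 1500),
#'                   dose = c(45, 90, 180, 360, 540))
#' cc <- build_calibration(pts)
#' predict(cc, 2000)
#' @export
build_calibration <- function(points,
                              model = c("rational", "monotone_spline", "netod_poly"),
                              unexposed_pixel_value = NULL) {
  model <- match.arg(model)
  points <- as.data.frame(points)
  need <- c("mu", "pixel_value", "dose")
  if (!all(need %in% names(points)))
    stop("'points' needs columns mu, pixel_value, dose")
  if (nrow(points) < 3L)
    stop(sprintf("need >= 3 calibration points, got %d", nrow(points)))
  if (any(points$mu <= 0) || any(points$dose <= 0))
    stop("mu and dose must be positive")
  fitpts <- points[order(points$dose), , drop = FALSE]
  if (!is.null(unexposed_pixel_value) && model != "netod_poly") {
    fitpts <- rbind(data.frame(mu = NA_real_,
                               pixel_value = as.numeric(unexposed_pixel_value),
                               dose = 0), fitpts)
  }
  pv <- fitpts$pixel_value
  dpv <- diff(pv)
  if (any(dpv == 0) || !(all(dpv > 0) || all(dpv < 0))) {
    bad <- which(c(FALSE, sign(dpv) != sign(dpv[1]) | dpv == 0))
    stop(sprintf(
      "calibration points are not strictly monotone: pixel values %g and %g (doses %g and %g cGy)",
      pv[bad[1] - 1L], pv[bad[1]], fitpts$dose[bad[1] - 1L], fitpts$dose[bad[1]]))
  }
  domain <- range(pv)
  fit <- switch(model,
                rational = fit_rational(fitpts, domain),
                monotone_spline = fit_monotone_spline(fitpts),
                netod_poly = fit_netod_poly(fitpts, unexposed_pixel_value))
  res <- fit$predict(pv) - fitpts$dose
  curve <- structure(list(points = fitpts, model = model,
                          params = fit$params,
                          domain = domain,
                          unexposed_pixel_value = unexposed_pixel_value,
                          residuals = res,
                          fit_tol = max(abs(res))),
                     class = "calibration_curve")
  check_curve_monotone(curve)
  curve
}

fit_rational <- function(pts, domain) {
  pv <- pts$pixel_value; dose <- pts$dose
  # exact solve on three spread points for starting values:
  # dose = a + b/(pv - c)
  i <- c(1L, ceiling(nrow(pts) / 2), nrow(pts))
  p <- pv[i]; d <- dose[i]
  # from the three equations: c is the root of a linear equation
  num <- d[1] * p[1] * (p[3] - p[2]) + d[2] * p[2] * (p[1] - p[3]) +
    d[3] * p[3] * (p[2] - p[1])
  den <- d[1] * (p[3] - p[2]) + d[2] * (p[1] - p[3]) + d[3] * (p[2] - p[1])
  start <- if (is.finite(num / den) && abs(den) > 0) {
    c0 <- num / den
    b0 <- (d[1] - d[2]) / (1 / (p[1] - c0) - 1 / (p[2] - c0))
    a0 <- d[1] - b0 / (p[1] - c0)
    list(a = a0, b = b0, c = c0)
  } else {
    list(a = 0, b = diff(range(dose)) * diff(range(pv)),
         c = domain[1] - diff(range(pv)))
  }
  if (start$c >= domain[1] && start$c <= domain[2]) {
    # push the pole just outside the data range on the nearer side
    w <- 0.05 * diff(domain)
    start$c <- if (abs(start$c - domain[1]) < abs(start$c - domain[2]))
      domain[1] - w else domain[2] + w
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(dose ~ a + b / (pixel_value - c), data = pts,
                      start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      stop(sprintf("rational calibration fit failed (%s); try model = 'monotone_spline'",
                   conditionMessage(e))))
  cf <- as.list(stats::coef(fit))
  if (cf$c >= domain[1] && cf$c <= domain[2])
    stop(sprintf(
      "rational calibration is non-monotone: pole c = %.4g lies inside the pixel domain [%g, %g]; try model = 'monotone_spline'",
      cf$c, domain[1], domain[2]))
  list(params = cf,
       predict = function(p) cf$a + cf$b / (p - cf$c))
}

fit_monotone_spline <- function(pts) {
  o <- order(pts$pixel_value)
  f <- stats::splinefun(pts$pixel_value[o], pts$dose[o], method = "hyman")
  list(params = list(x = pts$pixel_value[o], y = pts$dose[o]), predict = f)
}

fit_netod_poly <- function(pts, unexposed) {
  if (is.null(unexposed))
    stop("model 'netod_poly' requires 'unexposed_pixel_value'")
  od <- log10(unexposed / pts$pixel_value)
  if (any(!is.finite(od)))
    stop("net optical density undefined: pixel values must be positive and below the unexposed value")
  fit <- stats::lm(dose ~ od + I(od^2), data = data.frame(dose = pts$dose, od = od))
  cf <- stats::coef(fit)
  list(params = as.list(cf),
       predict = function(p) {
         odp <- log10(unexposed / p)
         cf[1] + cf[2] * odp + cf[3] * odp^2
       })
}

curve_fun <- function(curve) {
  switch(curve$model,
         rational = {
           cf <- curve$params
           function(p) cf$a + cf$b / (p - cf$c)
         },
         monotone_spline = {
           stats::splinefun(curve$params$x, curve$params$y, method = "hyman")
         },
         netod_poly = {
           cf <- curve$params; un <- curve$unexposed_pixel_value
           function(p) {
             odp <- log10(un / p)
             cf[[1]] + cf[[2]] * odp + cf[[3]] * odp^2
           }
         })
}

check_curve_monotone <- function(curve, n = 512L) {
  f <- curve_fun(curve)
  g <- seq(curve$domain[1], curve$domain[2], length.out = n)
  dd <- diff(f(g))
  if (any(dd == 0) || !(all(dd > 0) || all(dd < 0)))
    stop(sprintf("fitted %s calibration is not strictly monotone over [%g, %g]",
                 curve$model, curve$domain[1], curve$domain[2]))
  invisible(TRUE)
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("calibration curve (%s): %d points, pixel domain [%g, %g]\n",
              x$model, nrow(x$points), x$domain[1], x$domain[2]))
  cat(sprintf("  dose range [%g, %g] cGy, max |residual| %.4g cGy\n",
              min(x$points$dose), max(x$points$dose), x$fit_tol))
  if (x$model == "rational")
    cat(sprintf("  dose = %.6g + %.6g / (pixel - %.6g)\n",
                x$params$a, x$params$b, x$params$c))
  invisible(x)
}

#' Evaluate a calibration curve
#'
#' @param object a `calibration_curve`.
#' @param pixel_values numeric vector of pixel values.
#' @param ... unused.
#' @return doses in cGy.
#' @export
predict.calibration_curve <- function(object, pixel_values, ...) {
  curve_fun(object)(pixel_values)
}

#' Invert a calibration curve
#'
#' Maps doses back to pixel values; used by the synthetic film generator.
#' For the rational model the inverse is closed-form; for the others a
#' monotone interpolant of the swapped coordinates on a dense grid is used.
#'
#' @param curve a `calibration_curve`.
#' @param doses numeric vector of doses (cGy) inside the curve's dose range.
#' @return pixel values.
#' @export
calibration_inverse <- function(curve, doses) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (curve$model == "rational") {
    cf <- curve$params
    return(cf$c + cf$b / (doses - cf$a))
  }
  f <- curve_fun(curve)
  g <- seq(curve$domain[1], curve$domain[2], length.out = 2048L)
  dg <- f(g)
  o <- order(dg)
  stats::splinefun(dg[o], g[o], method = "hyman")(doses)
}

#' Convert a film scan to a dose plane via a calibration curve
#'
#' Maps every pixel of the scan's ROI through the calibration.  The result
#' inherits its grid spacing from the scan dpi and its SDD from the scan
#' (56.8 cm for tray irradiations); doses are on the TPS / 100 cm scale by
#' construction of the curve.  The grid is centered so that the ROI center
#' sits on the beam central axis; residual placement error is handled by
#' [coregister()].
#'
#' Pixels outside the curve's domain are handled per side.  Excursions past
#' the low-dose edge (the unexposed-film end: scan background and noise)
#' are clamped to that edge and logged; they carry no dose information to
#' lose.  Excursions past the high-dose edge would silently truncate real
#' dose, so they are clamped only when they are at most `max_out_fraction`
#' of the ROI -- more than that is an error, since it means the scan and
#' calibration do not belong together.  Tiny negative doses from the
#' zero-dose end of the model are clipped to 0.
#'
#' @param scan a `film_scan`.
#' @param curve a `calibration_curve`.
#' @param max_out_fraction largest tolerated fraction of pixels beyond the
#'   high-dose domain edge (default 0.01).
#' @return a `dose_plane` (attribute `"steps"` carries the provenance log).
#' @export
apply_calibration <- function(scan, curve, max_out_fraction = 0.01) {
  stopifnot(inherits(scan, "film_scan"), inherits(curve, "calibration_curve"))
  r <- scan$roi
  px <- scan$pixels[r[1]:r[2], r[3]:r[4], drop = FALSE]
  f <- curve_fun(curve)
  # which domain edge carries the higher dose depends on digitizer polarity
  edge_doses <- f(curve$domain)
  hi_edge <- curve$domain[which.max(edge_doses)]
  lo_edge <- curve$domain[which.min(edge_doses)]
  out_hi <- if (hi_edge > lo_edge) px > hi_edge else px < hi_edge
  out_lo <- if (lo_edge < hi_edge) px < lo_edge else px > lo_edge
  n_hi <- sum(out_hi); n_lo <- sum(out_lo)
  if (n_hi > max_out_fraction * length(px))
    stop(sprintf(
      "%d of %d pixels (%.1f%%) fall beyond the high-dose edge of the calibration domain [%g, %g]; scan and calibration are inconsistent",
      n_hi, length(px), 100 * n_hi / length(px),
      curve$domain[1], curve$domain[2]))
  pxc <- pmin(pmax(px, curve$domain[1]), curve$domain[2])
  dose <- f(pxc)
  n_neg <- sum(dose < 0)
  dose[dose < 0] <- 0
  sp <- scan_pixel_spacing(scan)
  steps <- c(scan$steps,
             sprintf("apply_calibration: model %s, domain [%g, %g]",
                     curve$model, curve$domain[1], curve$domain[2]),
             if (n_lo > 0) sprintf("apply_calibration: clamped %d pixels past the low-dose (background) edge", n_lo),
             if (n_hi > 0) sprintf("apply_calibration: clamped %d pixels past the high-dose edge", n_hi),
             if (n_neg > 0) sprintf("apply_calibration: clipped %d small negative doses to 0", n_neg))
  pl <- dose_plane(matrix(dose, nrow = nrow(px)), spacing = sp,
                   sdd = scan$sdd, label = "film")
  attr(pl, "steps") <- steps
  pl
}

#' Serialize a calibration curve to JSON
#'
#' @param curve a `calibration_curve`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_calibration <- function(curve, path) {
  stopifnot(inherits(curve, "calibration_curve"))
  obj <- list(format = "rcfqa_calibration", version = 1L,
              model = curve$model,
              points = curve$points,
              params = curve$params,
              domain = curve$domain,
              unexposed_pixel_value = curve$unexposed_pixel_value,
              residuals = curve$residuals,
              fit_tol = curve$fit_tol)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a calibration curve from JSON
#'
#' @param path file written by [write_calibration()].
#' @return a `calibration_curve`.
#' @export
read_calibration <- function(path) {
  if (!file.exists(path)) stop(sprintf("calibration file not found: '%s'", path))
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "rcfqa_calibration"))
    stop(sprintf("'%s' is not an rcfqa calibration file", path))
  pts <- as.data.frame(obj$points)
  # refit from the stored points: guarantees the in-memory model and its
  # monotonicity check, independent of serialization precision
  build_calibration(pts[!is.na(pts$mu), , drop = FALSE], model = obj$model,
                    unexposed_pixel_value = obj$unexposed_pixel_value)
}
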