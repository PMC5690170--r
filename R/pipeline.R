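#' Full transmission-QA analysis of a film scan against a TPS plane
#'
#' Runs the complete comparison chain and issues the verdict:
#' \enumerate{
#'   \item convert the scan to dose via the calibration curve;
#'   \item project the film plane from its SDD (56.8 cm on the tray) to the
#'     TPS plane's SDD along the beam divergence;
#'   \item estimate the registration to the TPS plane on the two central
#'     profiles (least-processed data);
#'   \item Gaussian-smooth the film plane on its native fine grid to
#'     suppress scan noise;
#'   \item resample both planes onto the comparison grid, carrying the film
#'     through the registration transform;
#'   \item extract the normalization-point doses and compute the percent
#'     difference;
#'   \item gamma analysis; by default the film plane is first rescaled to
#'     match the TPS dose at the normalization point, so the gamma test
#'     judges the shape of the distribution while the point-dose criterion
#'     judges its absolute level (a uniform monitor-unit error then shows
#'     the characteristic signature: high gamma pass rate, large percent
#'     difference);
#'   \item apply the Pass/Fail policy.
#' }
#' Registration is performed before smoothing (align on least-processed
#' data); every step and parameter is logged in the result's `steps`.
#'
#' @param scan a `film_scan` (or a pre-calibrated film `dose_plane`).
#' @param tps_plane the TPS `dose_plane` (reference).
#' @param curve a `calibration_curve` (ignored when `scan` is already a
#'   `dose_plane`).
#' @param policy a [qa_policy()].
#' @param sigma smoothing kernel SD in mm (default 1).
#' @param target_spacing comparison-grid spacing in mm (default 0.5, the
#'   interpolation used in the methodology; coarser values trade precision
#'   for speed).
#' @param search coregistration search half-window in mm (default 10).
#' @param manual_shift optional manual registration `c(dx, dy)` mm.
#' @param norm_point normalization-point coordinates in mm (default the
#'   central axis).
#' @param window point-dose averaging window in mm (default 2).
#' @param gamma_relative rescale the film plane to the TPS
#'   normalization-point dose before gamma (default TRUE).
#' @return a `qa_result`.
#' @examples
#' \donttest{
#' tps <- make_square_field(10)
#' pts <- synthetic_calibration(seed = 7)
#' curve <- build_calibration(pts)
#' scan <- simulate_film_scan(tps, seed = 8)
#' qa_analyze(scan, tps, curve, target_spacing = 1)
#' }
#' @export
qa_analyze <- function(scan, tps_plane, curve = NULL, policy = qa_policy(),
                       sigma = 1, target_spacing = 0.5, search = 10,
                       manual_shift = NULL, norm_point = c(0, 0), window = 2,
                       gamma_relative = TRUE) {
  stopifnot(inherits(tps_plane, "dose_plane"), inherits(policy, "qa_policy"))
  if (inherits(scan, "film_scan")) {
    if (is.null(curve)) stop("a calibration curve is required for a film scan")
    film <- apply_calibration(scan, curve)
  } else if (inherits(scan, "dose_plane")) {
    film <- scan
  } else stop("'scan' must be a film_scan or a dose_plane")
  film <- project_to_isocenter(film, tps_plane$sdd)
  t <- coregister(tps_plane, film, search = search,
                  manual_shift = manual_shift)
  # smooth on the film's native (fine) grid, then carry it into the
  # reference frame on the comparison grid in one resampling pass
  film <- gaussian_smooth(film, sigma)
  ref <- resample_linear(tps_plane, target_spacing)
  film <- apply_transform(film, t, target = ref)
  dose_tps <- extract_point_dose(ref, norm_point, window)
  dose_film <- extract_point_dose(film, norm_point, window)
  steps <- c(attr(film, "steps"),
             sprintf("extract_point_dose: point (%g, %g) mm, window %g mm",
                     norm_point[1], norm_point[2], window))
  ev <- film
  if (gamma_relative) {
    if (!is.finite(dose_film) || dose_film <= 0)
      stop("film dose at the normalization point is not positive; cannot renormalize")
    f <- dose_tps / dose_film
    ev <- dose_plane(film$values * f, spacing = film$spacing,
                     origin = film$origin, sdd = film$sdd, label = film$label)
    steps <- c(steps,
               sprintf("gamma renormalization: film scaled by %.5f to the TPS normalization-point dose", f))
  }
  crit <- policy$gamma
  if (crit$normalization == "point_dose") crit$norm_point <- norm_point
  g <- gamma_map(ref, ev, crit)
  steps <- c(steps,
             sprintf("gamma_map: %g%%/%g mm, threshold %g%%, %s, pass rate %.2f%%",
                     crit$dose_tol, crit$dta_tol, 100 * crit$threshold,
                     crit$normalization, g$pass_rate))
  evaluate_qa(dose_film, dose_tps, g, policy, steps = steps)
}
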