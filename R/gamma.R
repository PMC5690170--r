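#' Gamma-index comparison of two dose planes
#'
#' For every reference point above the low-dose threshold, the gamma index
#' is the minimum over nearby evaluated positions of
#' `sqrt(dist^2 / dta^2 + dDose^2 / delta^2)`, with `dDose` expressed in %
#' of the normalization dose and `delta` the dose-difference criterion.
#' Points with `gamma <= 1` agree within the combined dose /
#' distance-to-agreement tolerance.  The evaluated plane is bilinearly
#' interpolated on a sub-grid with step at most `dta_tol / 10` for the
#' spatial search, which is bounded at
#' `search_radius_factor * dta_tol` (beyond it gamma exceeds the factor and
#' cannot change agreement status).
#'
#' Reference points below threshold, and points where the evaluated plane
#' has no data anywhere in the search radius, carry the `NA` sentinel and
#' are excluded from the pass-rate denominator.
#'
#' @param reference a `dose_plane` (the TPS plane).
#' @param evaluated a `dose_plane` at the same SDD (the film plane).
#' @param criteria a [gamma_criteria()] object.
#' @param substep spatial sampling step of the search sub-grid in mm
#'   (default `dta_tol / 10`; halving it is a convergence check and should
#'   leave the pass rate essentially unchanged).
#' @return an object of class `gamma_result`: `gamma` (matrix on the
#'   reference grid, `NA` = not evaluated), `pass_rate` (% of evaluated
#'   points with gamma <= 1), `n_evaluated`, `norm_dose` (cGy) and the
#'   `criteria` used.
#' @examples
#' ref <- dose_plane(matrix(200, 21, 21), spacing = 2)
#' ev <- dose_plane(matrix(204, 21, 21), spacing = 2)
#' gamma_map(ref, ev, gamma_criteria())$pass_rate  # 2% off -> gamma 2/3
#' @export
gamma_map <- function(reference, evaluated, criteria = gamma_criteria(),
                      substep = criteria$dta_tol / 10) {
  g <- gamma_setup(reference, evaluated, criteria, substep)
  den <- g$norm_dose * criteria$dose_tol / 100
  o <- order(g$dist2)
  gm <- .gamma_search_cpp(g$ref_masked, g$fine, g$row0, g$col0, g$ky, g$kx,
                          g$di[o], g$dj[o], g$dist2[o], den)
  gamma_result_from_map(gm, reference, criteria, g$norm_dose)
}

#' Exhaustive-search gamma oracle
#'
#' Same contract as [gamma_map()], computed in pure R by scanning every
#' fine-grid position within the search radius for every reference point,
#' with no pruning or early exit.  It is the correctness standard the fast
#' search is tested against, and is restricted to small grids.
#'
#' @inheritParams gamma_map
#' @param max_dim refuse reference grids with more than this many rows or
#'   columns (default 60).
#' @return a `gamma_result`.
#' @export
gamma_oracle <- function(reference, evaluated, criteria = gamma_criteria(),
                         substep = criteria$dta_tol / 10, max_dim = 60L) {
  d <- dim(reference$values)
  if (any(d > max_dim))
    stop(sprintf("gamma_oracle is for small grids (<= %d per axis), got %d x %d",
                 max_dim, d[1], d[2]))
  g <- gamma_setup(reference, evaluated, criteria, substep)
  den <- g$norm_dose * criteria$dose_tol / 100
  dta2 <- criteria$dta_tol^2
  R2 <- (criteria$search_radius_factor * criteria$dta_tol)^2
  fny <- nrow(g$fine); fnx <- ncol(g$fine)
  gm <- matrix(NA_real_, d[1], d[2])
  for (j in seq_len(d[2])) {
    for (i in seq_len(d[1])) {
      d_ref <- g$ref_masked[i, j]
      if (is.na(d_ref)) next
      fi0 <- g$row0 + (i - 1L) * g$ky   # 0-based
      fj0 <- g$col0 + (j - 1L) * g$kx
      ii <- seq.int(max(0L, fi0 - g$mi), min(fny - 1L, fi0 + g$mi))
      jj <- seq.int(max(0L, fj0 - g$mj), min(fnx - 1L, fj0 + g$mj))
      dy2 <- ((ii - fi0) * g$sy)^2
      dx2 <- ((jj - fj0) * g$sx)^2
      dist2 <- outer(dy2, dx2, `+`)
      vals <- g$fine[ii + 1L, jj + 1L, drop = FALSE]
      keep <- dist2 <= R2 & !is.na(vals)
      if (!any(keep)) next
      g2 <- dist2[keep] / dta2 + ((vals[keep] - d_ref) / den)^2
      gm[i, j] <- sqrt(min(g2))
    }
  }
  gamma_result_from_map(gm, reference, criteria, g$norm_dose)
}

# Shared preparation: normalization dose, threshold mask, aligned fine grid
# of the evaluated plane, and the integer search neighbourhood.
gamma_setup <- function(reference, evaluated, criteria,
                        substep = criteria$dta_tol / 10) {
  stopifnot(inherits(reference, "dose_plane"), inherits(evaluated, "dose_plane"),
            inherits(criteria, "gamma_criteria"))
  if (abs(reference$sdd - evaluated$sdd) > 1e-6)
    stop(sprintf("planes live at different SDDs (%.4g vs %.4g cm); project first",
                 reference$sdd, evaluated$sdd))
  norm_dose <- switch(criteria$normalization,
                      global_max = max(reference$values, na.rm = TRUE),
                      point_dose = plane_value_at(reference,
                                                  criteria$norm_point[1],
                                                  criteria$norm_point[2]))
  if (!is.finite(norm_dose) || norm_dose <= 0)
    stop("normalization dose is not positive")
  thr <- criteria$threshold * norm_dose
  ref_masked <- reference$values
  ref_masked[is.na(ref_masked) | ref_masked < thr] <- NA_real_
  if (all(is.na(ref_masked)))
    stop("threshold excludes everything: no reference point reaches it")
  # fine sub-grid aligned with the reference nodes, step <= substep
  if (!is.finite(substep) || substep <= 0) stop("'substep' must be > 0 (mm)")
  kx <- max(1L, as.integer(ceiling(reference$spacing[1] / substep)))
  ky <- max(1L, as.integer(ceiling(reference$spacing[2] / substep)))
  sx <- reference$spacing[1] / kx
  sy <- reference$spacing[2] / ky
  R <- criteria$search_radius_factor * criteria$dta_tol
  mj <- as.integer(ceiling(R / sx))
  mi <- as.integer(ceiling(R / sy))
  rax <- plane_axes(reference)
  fx <- rax$x[1] + (seq_len((length(rax$x) - 1L) * kx + 2L * mj + 1L) - 1L - mj) * sx
  fy <- rax$y[1] + (seq_len((length(rax$y) - 1L) * ky + 2L * mi + 1L) - 1L - mi) * sy
  fine <- interp_masked(evaluated, fx, fy)
  off <- expand.grid(di = -mi:mi, dj = -mj:mj)
  d2 <- (off$di * sy)^2 + (off$dj * sx)^2
  keep <- d2 <= R^2
  list(ref_masked = ref_masked, fine = fine, norm_dose = norm_dose,
       row0 = mi, col0 = mj, ky = ky, kx = kx, mi = mi, mj = mj,
       sx = sx, sy = sy,
       di = off$di[keep], dj = off$dj[keep],
       dist2 = d2[keep] / criteria$dta_tol^2)
}

# bilinear sampling of a plane on arbitrary axes, NA outside its extent
interp_masked <- function(plane, xs, ys) {
  ext <- plane_extent(plane)
  tol <- 1e-9
  xin <- xs >= ext$x[1] - tol & xs <= ext$x[2] + tol
  yin <- ys >= ext$y[1] - tol & ys <= ext$y[2] + tol
  out <- matrix(NA_real_, length(ys), length(xs))
  if (any(xin) && any(yin)) {
    g <- expand.grid(x = xs[xin], y = ys[yin])
    out[yin, xin] <- matrix(plane_value_at(plane, g$x, g$y),
                            nrow = sum(yin), byrow = TRUE)
  }
  out
}

gamma_result_from_map <- function(gm, reference, criteria, norm_dose) {
  n_eval <- sum(!is.na(gm))
  if (n_eval == 0L)
    stop("no reference point could be evaluated (no evaluated data in range)")
  structure(list(gamma = gm,
                 pass_rate = 100 * sum(gm <= 1, na.rm = TRUE) / n_eval,
                 n_evaluated = n_eval,
                 norm_dose = norm_dose,
                 spacing = reference$spacing,
                 origin = reference$origin,
                 criteria = criteria),
            class = "gamma_result")
}

#' @export
print.gamma_result <- function(x, ...) {
  cat(sprintf("gamma result (%g%% / %g mm, threshold %g%%, %s): pass rate %.1f%% (%d points)\n",
              x$criteria$dose_tol, x$criteria$dta_tol,
              100 * x$criteria$threshold, x$criteria$normalization,
              x$pass_rate, x$n_evaluated))
  gs <- x$gamma[!is.na(x$gamma)]
  cat(sprintf("  gamma mean %.3f, max %.3f; normalization dose %.2f cGy\n",
              mean(gs), max(gs), x$norm_dose))
  invisible(x)
}

#' Export a gamma map as an ascii_grid file
#'
#' @param result a `gamma_result`.
#' @param path output path (`NA` marks not-evaluated points).
#' @param sdd SDD recorded in the header (default 100).
#' @return `path`, invisibly.
#' @export
write_gamma_map <- function(result, path, sdd = 100) {
  stopifnot(inherits(result, "gamma_result"))
  pl <- dose_plane(ifelse(is.na(result$gamma), NA_real_, result$gamma),
                   spacing = result$spacing, origin = result$origin,
                   sdd = sdd, label = "gamma map (unitless)")
  write_dose_grid(pl, path)
}
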