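## Unconfined-compression analytics: engineering stress-strain conversion and
## Young's modulus extraction from an automatically detected linear region.

#' Engineering stress-strain curve
#'
#' @param strain engineering strain (dimensionless, `dh/h0`), strictly
#'   increasing, within `[0, 0.5]`.
#' @param stress_pa engineering stress (Pa, `F/A0`).
#' @param meta optional list of sample metadata (gel concentration,
#'   equilibration day, ...).
#' @return data frame of class `stress_strain_curve` with columns `strain`,
#'   `stress_pa`.
#' @export
stress_strain_curve <- function(strain, stress_pa, meta = list()) {
  if (length(strain) != length(stress_pa))
    stop("'strain' and 'stress_pa' must have equal length")
  if (length(strain) < 10L) stop("need at least 10 points")
  if (any(diff(strain) <= 0)) stop("'strain' must be strictly increasing")
  if (min(strain) < 0 || max(strain) > 0.5)
    stop("engineering strain must lie in [0, 0.5]")
  structure(data.frame(strain = strain, stress_pa = stress_pa),
            meta = meta, E_true = meta$E_true,
            class = c("stress_strain_curve", "data.frame"))
}

#' Convert a force-displacement record to engineering stress-strain
#'
#' Uses the initial-configuration (engineering) convention for a cylindrical
#' sample: `stress = F / (pi d^2 / 4)`, `strain = displacement / height`.
#' The reference geometry is a gel disk cut with a biopsy punch: diameter
#' `d` and height `h` in mm, force in N; stress comes out in Pa.
#'
#' @param force_n force, N.
#' @param displacement_mm platen displacement, mm, strictly increasing.
#' @param diameter_mm sample diameter, mm (default 6).
#' @param height_mm sample height, mm (default 2).
#' @param meta sample metadata list.
#' @return a [stress_strain_curve].
#' @export
force_to_stress_strain <- function(force_n, displacement_mm, diameter_mm = 6,
                                   height_mm = 2, meta = list()) {
  if (diameter_mm <= 0 || height_mm <= 0)
    stop("'diameter_mm' and 'height_mm' must be > 0")
  if (length(force_n) != length(displacement_mm))
    stop("'force_n' and 'displacement_mm' must have equal length")
  if (any(diff(displacement_mm) <= 0))
    stop("input error: displacement must be strictly increasing")
  area_m2 <- pi * (diameter_mm * 1e-3)^2 / 4
  stress_strain_curve(displacement_mm / height_mm, force_n / area_m2,
                      meta = meta)
}

#' Detect the linear region of a stress-strain curve
#'
#' Scans contiguous windows of strain width at least `min_strain_width` on a
#' `grid x grid` lattice of onsets and widths and returns the window that
#' maximizes the coefficient of determination of an ordinary least-squares
#' line; ties (within `1e-10`) are broken toward the widest window, then the
#' latest onset. This automates the manual cropping of compression records to
#' their approximately linear region.
#'
#' @param curve a [stress_strain_curve].
#' @param min_strain_width minimum strain extent of the window (default 0.1).
#' @param grid number of candidate onsets and widths (default 50).
#' @param r2_min windows are only acceptable above this R-squared; when no
#'   window reaches it (flat or pure-noise curves) a degenerate-fit error is
#'   raised. Default 0.5.
#' @return list with `region` (index pair into the curve), `r_squared`, and
#'   `strain_range`.
#' @export
detect_linear_region <- function(curve, min_strain_width = 0.1, grid = 50L,
                                 r2_min = 0.5) {
  stopifnot(inherits(curve, "stress_strain_curve"))
  strain <- curve$strain; stress <- curve$stress_pa
  span <- max(strain) - min(strain)
  if (min_strain_width >= span)
    stop("'min_strain_width' must be smaller than the strain span")
  if (stats::var(stress) == 0)
    stop("degenerate-fit error: stress has zero variance")
  onsets <- seq(min(strain), max(strain) - min_strain_width,
                length.out = grid)
  widths <- seq(min_strain_width, span, length.out = grid)
  best <- list(r2 = -Inf, lo = NA_integer_, hi = NA_integer_, width = -Inf,
               onset = -Inf)
  for (w in widths) for (o in onsets) {
    if (o + w > max(strain) + 1e-12) next
    lo <- findInterval(o - 1e-12, strain) + 1L
    hi <- findInterval(o + w + 1e-12, strain)
    if (hi - lo + 1L < 3L) next
    r2 <- window_r2(strain, stress, lo, hi)
    if (is.na(r2)) next
    better <- r2 > best$r2 + 1e-10 ||
      (abs(r2 - best$r2) <= 1e-10 &&
         (w > best$width + 1e-12 ||
            (abs(w - best$width) <= 1e-12 && o > best$onset)))
    if (better) best <- list(r2 = r2, lo = lo, hi = hi, width = w, onset = o)
  }
  if (!is.finite(best$r2) || best$r2 < r2_min)
    stop("degenerate-fit error: no window with R^2 >= ", r2_min,
         " (best ", signif(max(best$r2, 0), 3), ")")
  list(region = c(best$lo, best$hi), r_squared = best$r2,
       strain_range = strain[c(best$lo, best$hi)])
}

window_r2 <- function(x, y, lo, hi) {
  xs <- x[lo:hi]; ys <- y[lo:hi]
  sxx <- sum((xs - mean(xs))^2)
  syy <- sum((ys - mean(ys))^2)
  if (syy == 0 || sxx == 0) return(NA_real_)
  sxy <- sum((xs - mean(xs)) * (ys - mean(ys)))
  sxy^2 / (sxx * syy)
}

#' Young's modulus from the linear region of a stress-strain curve
#'
#' Ordinary least-squares slope of stress against strain over the given
#' region; the intercept is free so any toe-region stress offset is absorbed.
#' When `region` is omitted it is found with [detect_linear_region()].
#'
#' @param curve a [stress_strain_curve].
#' @param region index pair `c(lo, hi)`; `NULL` to auto-detect.
#' @param ... passed to [detect_linear_region()].
#' @return object of class `modulus_fit`: list with `E` (Pa), `region`,
#'   `r_squared`, `n_points`.
#' @export
young_modulus <- function(curve, region = NULL, ...) {
  stopifnot(inherits(curve, "stress_strain_curve"))
  if (is.null(region)) {
    det <- detect_linear_region(curve, ...)
    region <- det$region
  }
  lo <- region[1L]; hi <- region[2L]
  if (hi - lo + 1L < 3L) stop("fit error: fewer than 3 points in region")
  xs <- curve$strain[lo:hi]; ys <- curve$stress_pa[lo:hi]
  fit <- stats::lm.fit(cbind(1, xs), ys)
  E <- unname(fit$coefficients[2L])
  if (!is.finite(E) || E <= 0)
    stop("fit error: non-positive slope in selected region")
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((ys - mean(ys))^2)
  structure(list(E = E, region = c(lo, hi),
                 r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
                 n_points = hi - lo + 1L),
            class = "modulus_fit")
}

#' @export
print.modulus_fit <- function(x, ...) {
  cat(sprintf("modulus_fit: E = %.4g Pa (%.3g kPa), R^2 = %.4f, %d points\n",
              x$E, x$E / 1000, x$r_squared, x$n_points))
  invisible(x)
}

#' Average modulus over replicate sample fits
#'
#' Per-concentration modulus reported as the arithmetic mean over individual
#' sample fits, mirroring how replicate compression samples are averaged.
#'
#' @param fits list of `modulus_fit` objects.
#' @return list with `E_mean` (Pa), `E_sem` (Pa), `n`.
#' @export
summarize_moduli <- function(fits) {
  e <- vapply(fits, function(f) f$E, numeric(1L))
  list(E_mean = mean(e),
       E_sem = if (length(e) > 1L) stats::sd(e) / sqrt(length(e)) else NA_real_,
       n = length(e))
}
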