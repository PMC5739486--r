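#' Fan-beam acquisition geometry
#'
#' A rotating point source with a flat (equally spaced) detector. Defaults
#' follow a common simulation setup for 200 mm slices: source and detector
#' both 400 mm from the rotation centre, a 413 mm detector with 512 bins,
#' and 1024 views uniformly covering 360 degrees. View v (0-based) is at
#' angle `angular_range_deg * v / n_views` with no endpoint duplication;
#' the source sits at that angle on a circle of radius
#' `dist_source_center_mm`, and detector bin centres are offset
#' `(b + 0.5 - n_bins/2) * detector_length_mm / n_bins` along the detector.
#'
#' At construction the fan coverage at the isocentre,
#' `(detector_length_mm / 2) * dso / (dso + dcd)`, is checked against the
#' 100 mm inscribed circle of the default 200 mm field of view; a narrower
#' fan triggers a warning (objects are assumed inside the scan circle).
#'
#' @param dist_source_center_mm source-to-rotation-centre distance (mm).
#' @param dist_center_detector_mm rotation-centre-to-detector distance (mm).
#' @param detector_length_mm total detector length (mm).
#' @param n_bins number of detector bins (>= 2).
#' @param n_views number of projection angles (>= 1).
#' @param angular_range_deg angular range, uniformly sampled.
#' @return an object of class `fan_geometry`.
#' @export
fan_geometry <- function(dist_source_center_mm = 400,
                         dist_center_detector_mm = 400,
                         detector_length_mm = 413,
                         n_bins = 512L, n_views = 1024L,
                         angular_range_deg = 360) {
  check_number(dist_source_center_mm, "dist_source_center_mm", 0, TRUE)
  check_number(dist_center_detector_mm, "dist_center_detector_mm", 0, TRUE)
  check_number(detector_length_mm, "detector_length_mm", 0, TRUE)
  check_number(angular_range_deg, "angular_range_deg", 0, TRUE)
  if (!is.numeric(n_bins) || n_bins < 2) stopf("'n_bins' must be >= 2")
  if (!is.numeric(n_views) || n_views < 1) stopf("'n_views' must be >= 1")
  g <- structure(list(dso = dist_source_center_mm,
                      dcd = dist_center_detector_mm,
                      det_len = detector_length_mm,
                      n_bins = as.integer(n_bins),
                      n_views = as.integer(n_views),
                      ang_range = angular_range_deg),
                 class = "fan_geometry")
  if (fan_coverage_radius(g) < 100)
    warning(sprintf(
      "fan covers only a %.1f mm radius at the isocentre; the default 200 mm FOV scan circle (100 mm) is truncated",
      fan_coverage_radius(g)), call. = FALSE)
  g
}

#' Radius (mm) of the circle at the isocentre covered by the fan
#' @param geom a [fan_geometry()].
#' @export
fan_coverage_radius <- function(geom) {
  (geom$det_len / 2) * geom$dso / (geom$dso + geom$dcd)
}

#' @export
print.fan_geometry <- function(x, ...) {
  cat(sprintf("fan_geometry: dso=%g mm, dcd=%g mm, detector %g mm / %d bins, %d views over %g deg\n",
              x$dso, x$dcd, x$det_len, x$n_bins, x$n_views, x$ang_range))
  invisible(x)
}

#' Construct a sinogram object
#'
#' @param values `n_views x n_bins` matrix of line integrals (mu * mm).
#' @param geometry a [fan_geometry()].
#' @param noisy whether the values are estimates from noisy counts.
#' @return an object of class `sinogram`.
#' @export
sinogram <- function(values, geometry, noisy = FALSE) {
  if (!inherits(geometry, "fan_geometry")) stopf("'geometry' must be a fan_geometry")
  if (!is.matrix(values) || nrow(values) != geometry$n_views ||
      ncol(values) != geometry$n_bins)
    stopf("sinogram must be %d x %d to match the geometry",
          geometry$n_views, geometry$n_bins)
  if (!noisy && (any(!is.finite(values)) || any(values < 0)))
    stopf("noiseless sinogram values must be finite and >= 0")
  structure(list(values = values, geometry = geometry, noisy = isTRUE(noisy)),
            class = "sinogram")
}

#' @export
print.sinogram <- function(x, ...) {
  cat(sprintf("sinogram: %d views x %d bins, %s, l in [%.4g, %.4g]\n",
              nrow(x$values), ncol(x$values),
              if (x$noisy) "noisy" else "noiseless",
              min(x$values), max(x$values)))
  invisible(x)
}
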