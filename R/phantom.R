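#' Describe a synthetic attenuation phantom
#'
#' A phantom spec is a declarative description of a 2-D slice of linear
#' attenuation coefficients: a uniform background plus a set of
#' (possibly rotated, possibly overlapping) ellipses, each adding a signed
#' attenuation increment. Units are attenuation per mm on a square grid of
#' `grid_n` pixels spanning `fov_mm` x `fov_mm` millimetres, with the grid
#' centre at the rotation centre, x rightward and y upward.
#'
#' @param grid_n pixels per side (>= 16).
#' @param fov_mm physical side length in mm.
#' @param ellipses data frame with columns `cx_mm`, `cy_mm`, `a_mm`, `b_mm`,
#'   `angle_deg`, `delta_mu` (one row per ellipse), or `NULL` for none.
#' @param background_mu uniform background attenuation (per mm, >= 0).
#' @param random optional list requesting randomized ellipses at generation
#'   time (see [random_phantom_spec()] for the fields); usually left `NULL`.
#' @return an object of class `phantom_spec`.
#' @seealso [generate_phantom()], [phantom_catalog()]
#' @export
phantom_spec <- function(grid_n = 256L, fov_mm = 200, ellipses = NULL,
                         background_mu = 0, random = NULL) {
  if (!is.numeric(grid_n) || length(grid_n) != 1L || grid_n < 16)
    stopf("invalid phantom spec: 'grid_n' must be a single integer >= 16")
  check_number(fov_mm, "fov_mm", 0, strict = TRUE)
  check_number(background_mu, "background_mu", 0)
  if (!is.null(ellipses)) {
    ellipses <- as.data.frame(ellipses)
    need <- c("cx_mm", "cy_mm", "a_mm", "b_mm", "angle_deg", "delta_mu")
    miss <- setdiff(need, names(ellipses))
    if (length(miss))
      stopf("invalid phantom spec: 'ellipses' lacks column(s) %s",
            paste(miss, collapse = ", "))
    if (nrow(ellipses) && any(ellipses$a_mm <= 0 | ellipses$b_mm <= 0))
      stopf("invalid phantom spec: 'ellipses' axes must be positive")
  }
  structure(list(grid_n = as.integer(grid_n), fov_mm = fov_mm,
                 ellipses = ellipses, background_mu = background_mu,
                 random = random),
            class = "phantom_spec")
}

#' Spec for a randomized multi-ellipse phantom
#'
#' Describes a family of phantoms: a soft-tissue-like background disk plus a
#' random number of internal ellipses with random centres, axes, orientations
#' and attenuation increments. The concrete ellipses are drawn when
#' [generate_phantom()] is called with a seed, so one spec plus a list of
#' seeds yields a reproducible dataset of distinct slices.
#'
#' Defaults emulate abdominal CT content: a body disk whose attenuation
#' (0.038/mm) is chosen so the peak line integrals through the slice match
#' the water-equivalent path lengths of a large abdomen (l up to about 8,
#' a transmitted fraction down to a few photons per ten thousand) despite
#' the disk being thinner than a real abdomen, a few low-contrast
#' soft-tissue ellipses (within about +/-0.012/mm of the body), and — like
#' every real abdominal slice, which always contains vertebra and ribs —
#' two or three small bone-like inserts (+0.03 to +0.042/mm). The dense
#' inserts matter: rays through them are photon-starved at low blank-scan
#' counts, which is what creates the radiating streak artifacts
#' characteristic of low-dose FBP images.
#'
#' @inheritParams phantom_spec
#' @param n_ellipses integer range `c(min, max)` of soft-tissue ellipses.
#' @param body_radius_mm radius of the background disk.
#' @param body_mu attenuation of the background disk (per mm).
#' @param delta_range range of soft-tissue attenuation increments (per mm).
#' @param axis_range_mm range of soft-tissue ellipse semi-axes (mm).
#' @param n_bones integer range of bone-like inserts per slice.
#' @param bone_delta range of bone attenuation increments (per mm).
#' @param bone_axis_mm range of bone insert semi-axes (mm).
#' @return a `phantom_spec` whose ellipses are drawn at generation time.
#' @export
random_phantom_spec <- function(grid_n = 256L, fov_mm = 200,
                                n_ellipses = c(3L, 8L),
                                body_radius_mm = 90, body_mu = 0.038,
                                delta_range = c(-0.012, 0.012),
                                axis_range_mm = c(5, 45),
                                n_bones = c(2L, 3L),
                                bone_delta = c(0.03, 0.042),
                                bone_axis_mm = c(6, 18)) {
  phantom_spec(grid_n = grid_n, fov_mm = fov_mm, ellipses = NULL,
               background_mu = 0,
               random = list(n_ellipses = as.integer(n_ellipses),
                             body_radius_mm = body_radius_mm,
                             body_mu = body_mu,
                             delta_range = delta_range,
                             axis_range_mm = axis_range_mm,
                             n_bones = as.integer(n_bones),
                             bone_delta = bone_delta,
                             bone_axis_mm = bone_axis_mm))
}

#' Rasterize a phantom spec into an attenuation image
#'
#' Each pixel takes the background value plus the sum of the increments of
#' all ellipses whose region contains the pixel centre (no anti-aliasing;
#' this makes ray-integral oracles exact against the same raster). Negative
#' sums are clipped to zero, so attenuation stays physical under arbitrary
#' overlaps.
#'
#' @param spec a [phantom_spec()].
#' @param seed integer seed used only when the spec requests randomized
#'   ellipses; the same (spec, seed) always yields the identical image.
#' @return an `attenuation_image`: list with `values` (grid_n x grid_n
#'   matrix, per mm), `pixel_size_mm` and `fov_mm`.
#' @export
generate_phantom <- function(spec, seed = NULL) {
  if (!inherits(spec, "phantom_spec")) stopf("'spec' must be a phantom_spec")
  ell <- spec$ellipses
  if (!is.null(spec$random)) {
    r <- spec$random
    drawn <- with_seed(seed, {
      ne <- if (length(r$n_ellipses) > 1L)
        sample(seq(r$n_ellipses[1], r$n_ellipses[2]), 1L) else r$n_ellipses
      body <- data.frame(cx_mm = 0, cy_mm = 0, a_mm = r$body_radius_mm,
                         b_mm = r$body_radius_mm, angle_deg = 0,
                         delta_mu = r$body_mu)
      out <- body
      if (ne > 0) {
        rad <- 0.7 * r$body_radius_mm * sqrt(runif(ne))
        th <- runif(ne, 0, 2 * pi)
        out <- rbind(out, data.frame(
          cx_mm = rad * cos(th), cy_mm = rad * sin(th),
          a_mm = runif(ne, r$axis_range_mm[1], r$axis_range_mm[2]),
          b_mm = runif(ne, r$axis_range_mm[1], r$axis_range_mm[2]),
          angle_deg = runif(ne, 0, 180),
          delta_mu = runif(ne, r$delta_range[1], r$delta_range[2])))
      }
      if (!is.null(r$n_bones)) {
        nb <- if (length(r$n_bones) > 1L)
          sample(seq(r$n_bones[1], r$n_bones[2]), 1L) else r$n_bones
        if (nb > 0) {
          rad <- 0.75 * r$body_radius_mm * sqrt(runif(nb))
          th <- runif(nb, 0, 2 * pi)
          out <- rbind(out, data.frame(
            cx_mm = rad * cos(th), cy_mm = rad * sin(th),
            a_mm = runif(nb, r$bone_axis_mm[1], r$bone_axis_mm[2]),
            b_mm = runif(nb, r$bone_axis_mm[1], r$bone_axis_mm[2]),
            angle_deg = runif(nb, 0, 180),
            delta_mu = runif(nb, r$bone_delta[1], r$bone_delta[2])))
        }
      }
      out
    })
    ell <- rbind(ell, drawn)
  }
  n <- spec$grid_n
  px <- spec$fov_mm / n
  # pixel-centre coordinates, origin at image centre, y upward, row 1 on top
  xs <- (seq_len(n) - 0.5 - n / 2) * px
  ys <- (n / 2 - (seq_len(n) - 0.5)) * px
  X <- matrix(xs, n, n, byrow = TRUE)
  Y <- matrix(ys, n, n)
  img <- matrix(spec$background_mu, n, n)
  if (!is.null(ell) && nrow(ell)) {
    for (i in seq_len(nrow(ell))) {
      e <- ell[i, ]
      a <- e$angle_deg * pi / 180
      xr <- (X - e$cx_mm) * cos(a) + (Y - e$cy_mm) * sin(a)
      yr <- -(X - e$cx_mm) * sin(a) + (Y - e$cy_mm) * cos(a)
      inside <- (xr / e$a_mm)^2 + (yr / e$b_mm)^2 <= 1
      img[inside] <- img[inside] + e$delta_mu
    }
  }
  img[img < 0] <- 0
  attenuation_image(img, spec$fov_mm)
}

#' Construct an attenuation image from a matrix
#'
#' @param values square matrix of non-negative attenuation coefficients
#'   (per mm); row 1 is the top of the slice.
#' @param fov_mm physical side length in mm.
#' @return an object of class `attenuation_image`.
#' @export
attenuation_image <- function(values, fov_mm) {
  if (!is.matrix(values) || nrow(values) != ncol(values))
    stopf("'values' must be a square matrix")
  if (any(!is.finite(values)) || any(values < 0))
    stopf("attenuation values must be finite and >= 0")
  check_number(fov_mm, "fov_mm", 0, strict = TRUE)
  structure(list(values = values, fov_mm = fov_mm,
                 pixel_size_mm = fov_mm / nrow(values)),
            class = "attenuation_image")
}

#' @export
print.attenuation_image <- function(x, ...) {
  cat(sprintf("attenuation_image: %dx%d px, %.4g mm FOV (%.4g mm/px), mu in [%.4g, %.4g]/mm\n",
              nrow(x$values), ncol(x$values), x$fov_mm, x$pixel_size_mm,
              min(x$values), max(x$values)))
  invisible(x)
}

#' Catalog of named reference phantoms
#'
#' Stable anchors used throughout the documentation and tests:
#' \describe{
#'   \item{disk}{uniform disk, radius 50 mm, 0.02/mm (water-like) on air.}
#'   \item{two_disk}{the same disk plus a 20 mm low-contrast insert
#'     (+0.004/mm) offset from centre.}
#'   \item{shepp}{a Shepp-Logan-style ten-ellipse head slice rescaled to
#'     attenuation-per-mm units.}
#' }
#'
#' @param name one of `"disk"`, `"two_disk"`, `"shepp"`.
#' @inheritParams phantom_spec
#' @return a `phantom_spec`.
#' @export
phantom_catalog <- function(name = c("disk", "two_disk", "shepp"),
                            grid_n = 256L, fov_mm = 200) {
  name <- match.arg(name)
  e <- function(cx, cy, a, b, ang, d)
    data.frame(cx_mm = cx, cy_mm = cy, a_mm = a, b_mm = b, angle_deg = ang,
               delta_mu = d)
  ell <- switch(name,
    disk = e(0, 0, 50, 50, 0, 0.02),
    two_disk = rbind(e(0, 0, 50, 50, 0, 0.02),
                     e(20, 10, 20, 20, 0, 0.004)),
    shepp = {
      # classic ellipse set, scaled: unit half-width -> 90 mm,
      # intensity 1 -> 0.02/mm
      s <- 90; m <- 0.02
      rbind(
        e(0, 0, 0.69 * s, 0.92 * s, 90, 1.0 * m),
        e(0, -0.0184 * s, 0.6624 * s, 0.874 * s, 90, -0.8 * m),
        e(0.22 * s, 0, 0.11 * s, 0.31 * s, 72, -0.2 * m),
        e(-0.22 * s, 0, 0.16 * s, 0.41 * s, 108, -0.2 * m),
        e(0, 0.35 * s, 0.21 * s, 0.25 * s, 90, 0.1 * m),
        e(0, 0.1 * s, 0.046 * s, 0.046 * s, 0, 0.1 * m),
        e(0, -0.1 * s, 0.046 * s, 0.046 * s, 0, 0.1 * m),
        e(-0.08 * s, -0.605 * s, 0.046 * s, 0.023 * s, 0, 0.1 * m),
        e(0, -0.605 * s, 0.023 * s, 0.023 * s, 0, 0.1 * m),
        e(0.06 * s, -0.605 * s, 0.023 * s, 0.046 * s, 0, 0.1 * m))
    })
  phantom_spec(grid_n = grid_n, fov_mm = fov_mm, ellipses = ell)
}

#' Serialize / restore phantom specs as JSON
#'
#' @param spec a `phantom_spec`.
#' @param path file path; for [phantom_spec_to_json()] `NULL` returns the
#'   JSON string instead of writing.
#' @return the JSON string (invisibly when written) or the restored spec.
#' @export
phantom_spec_to_json <- function(spec, path = NULL) {
  if (!inherits(spec, "phantom_spec")) stopf("'spec' must be a phantom_spec")
  js <- jsonlite::toJSON(unclass(spec), auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(as.character(js))
}

#' @rdname phantom_spec_to_json
#' @export
phantom_spec_from_json <- function(path) {
  x <- jsonlite::fromJSON(path)
  phantom_spec(grid_n = x$grid_n, fov_mm = x$fov_mm,
               ellipses = x$ellipses, background_mu = x$background_mu,
               random = x$random)
}
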