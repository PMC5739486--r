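#' Siddon ray-driven fan-beam projection
#'
#' Computes, for every (view, bin) pair, the exact radiological path of the
#' ray from the source position to the detector bin centre through the pixel
#' raster: the sum over traversed pixels of intersection length (mm) times
#' pixel attenuation (per mm). The traversal is the exact parametric
#' pixel-crossing walk, so line integrals are exact for the piecewise
#' constant raster (no interpolation). Rays that miss the image support
#' contribute zero.
#'
#' @param image an [attenuation_image()] centred at the rotation centre.
#' @param geom a [fan_geometry()].
#' @return a noiseless [sinogram()].
#' @export
siddon_project <- function(image, geom) {
  if (!inherits(image, "attenuation_image"))
    stopf("'image' must be an attenuation_image")
  if (!inherits(geom, "fan_geometry")) stopf("'geom' must be a fan_geometry")
  if (any(!is.finite(image$values)))
    stopf("image contains non-finite values")
  vals <- siddon_project_cpp(image$values, image$fov_mm, geom$dso, geom$dcd,
                             geom$det_len, geom$n_bins, geom$n_views,
                             geom$ang_range)
  sinogram(vals, geom, noisy = FALSE)
}
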