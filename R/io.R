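#' Read and write float images
#'
#' Images (attenuation maps, reconstructions, sinograms-as-matrices) are
#' stored as single-channel 32-bit float TIFF, a container every scientific
#' image stack reads. TIFF float storage is unit-range, so the values are
#' written affinely mapped to `[0, 1]` and the original range is recorded
#' in a JSON sidecar (`<path>.json`) together with any user metadata;
#' [read_float_image()] undoes the mapping, so the round trip is lossless
#' up to 32-bit float precision. Reading a float TIFF that lacks a sidecar
#' returns the stored unit-range values as-is.
#'
#' @param values numeric matrix.
#' @param path output path (`.tif`/`.tiff`).
#' @param meta optional list of metadata (e.g. field of view or acquisition
#'   geometry) merged into the JSON sidecar.
#' @return `write_float_image()` returns `path` invisibly;
#'   `read_float_image()` returns a list with `values` and `meta`
#'   (`NULL` when no sidecar is present).
#' @export
write_float_image <- function(values, path, meta = NULL) {
  if (!is.matrix(values)) stopf("'values' must be a matrix")
  if (any(!is.finite(values))) stopf("'values' must be finite")
  lo <- min(values)
  hi <- max(values)
  scale <- if (hi > lo) hi - lo else 1
  tiff::writeTIFF((values - lo) / scale, path, bits.per.sample = 32L,
                  reduce = FALSE)
  side <- c(list(value_range = c(lo, hi)), meta)
  writeLines(jsonlite::toJSON(side, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE),
             paste0(path, ".json"))
  invisible(path)
}

#' @rdname write_float_image
#' @export
read_float_image <- function(path) {
  v <- tiff::readTIFF(path, as.is = FALSE)
  if (length(dim(v)) == 3L) v <- v[, , 1L]
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::fromJSON(side) else NULL
  if (!is.null(meta$value_range)) {
    lo <- meta$value_range[1]
    hi <- meta$value_range[2]
    if (hi > lo) v <- v * (hi - lo) + lo else v <- v + lo
    meta$value_range <- NULL
    if (length(meta) == 0L) meta <- NULL
  }
  list(values = v, meta = meta)
}

#' Export an image as 8-bit PNG with explicit windowing
#'
#' Values are linearly mapped from `window = c(lo, hi)` to 0..255 and
#' clipped; the default window is the image range.
#'
#' @param values numeric matrix.
#' @param path output `.png` path.
#' @param window numeric `c(lo, hi)` display window.
#' @export
write_png_preview <- function(values, path, window = range(values)) {
  lo <- window[1]; hi <- window[2]
  if (hi <= lo) hi <- lo + 1e-12
  v <- pmin(pmax((values - lo) / (hi - lo), 0), 1)
  png::writePNG(v, path)
  invisible(path)
}
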