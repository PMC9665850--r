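#' Binary mask container
#'
#' Wraps a logical raster together with the channel it was computed from,
#' the thresholding method, and the resolved parameters, so downstream
#' tables can report exactly how each mask was produced.
#'
#' @param raster Logical matrix.
#' @param source_channel `"dna"` or `"marker"`.
#' @param method `"bernsen"` or `"global"`.
#' @param params Named list of the parameters used.
#' @return Object of class `binary_mask`.
#' @export
binary_mask <- function(raster, source_channel = "dna",
                        method = c("bernsen", "global"), params = list()) {
  stopifnot(is.logical(raster), is.matrix(raster))
  structure(list(raster = raster, source_channel = source_channel,
                 method = match.arg(method), params = params),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %dx%d, %s on %s channel, %d foreground px\n",
              nrow(x$raster), ncol(x$raster), x$method, x$source_channel,
              sum(x$raster)))
  invisible(x)
}

mask_raster <- function(mask) {
  if (inherits(mask, "binary_mask")) mask$raster else mask
}

#' Bernsen local adaptive threshold
#'
#' Binarizes an integer raster with the Bernsen method: each pixel is
#' compared against the midpoint of the minimum and maximum intensity in a
#' circular neighborhood of the given radius (disk including the center,
#' clipped at the image border). Where the local contrast `max - min` falls
#' below the contrast parameter, the neighborhood is considered homogeneous
#' and the whole region is set by comparing the midpoint against half of
#' the full intensity scale (128 for 8-bit, 32768 for 16-bit).
#'
#' The automatic counting regime uses radius 15 and contrast 35.
#'
#' @param image Integer matrix.
#' @param radius Neighborhood radius in pixels (>= 1).
#' @param contrast Local-contrast threshold in intensity units (>= 0;
#'   0 forces the midpoint comparison everywhere).
#' @param bit_depth 8 or 16; fixes the half-scale used in low-contrast
#'   regions.
#' @return A [binary_mask()] where foreground means `intensity > midpoint`
#'   (high-contrast pixels) or `midpoint >= half-scale` (low-contrast
#'   pixels).
#' @export
bernsen_threshold <- function(image, radius = 15L, contrast = 35,
                              bit_depth = 8L) {
  image <- as_intensity_matrix(image)
  if (radius < 1)
    stop_netquant("radius must be >= 1", "netquant_parameter_error")
  if (radius > max(dim(image)))
    stop_netquant("radius exceeds both image dimensions",
                  "netquant_parameter_error")
  if (contrast < 0)
    stop_netquant("contrast must be >= 0", "netquant_parameter_error")
  half_scale <- 2^(as.integer(bit_depth) - 1L)
  raster <- cpp_bernsen(image, as.integer(radius), as.numeric(contrast),
                        half_scale)
  binary_mask(raster, method = "bernsen",
              params = list(radius = as.integer(radius),
                            contrast = as.numeric(contrast),
                            bit_depth = as.integer(bit_depth)))
}

#' Global intensity threshold
#'
#' Manual-regime binarization: foreground where `intensity > t` (strict),
#' chosen so that the weaker staining of resting cell nuclei falls below
#' the cutoff.
#'
#' @param image Integer matrix.
#' @param t Threshold in intensity units, `0 <= t <=` max representable
#'   value.
#' @return A [binary_mask()].
#' @export
global_threshold <- function(image, t) {
  image <- as_intensity_matrix(image)
  if (t < 0)
    stop_netquant("threshold must be >= 0", "netquant_parameter_error")
  binary_mask(image > t, method = "global", params = list(t = t))
}
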