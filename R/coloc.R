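#' Manders overlap coefficient between two channels
#'
#' Computes `R = sum(a_i * b_i) / sqrt(sum(a_i^2) * sum(b_i^2))` over the
#' raw intensities of the two channels, optionally restricted to a region
#' of interest. By the Cauchy-Schwarz inequality `R` lies in `[0, 1]`: 1
#' for proportional channels, 0 for disjoint support. No background
#' subtraction or channel thresholding is applied; restrict via `roi` if
#' background handling is needed.
#'
#' @param ch1,ch2 Numeric matrices (or vectors) of identical shape.
#' @param roi Optional [binary_mask()] or logical matrix selecting the
#'   pixels to include.
#' @return List of class `overlap_result` with `coefficient`, `n_pixels`
#'   and `channel_pair`.
#' @export
overlap_coefficient <- function(ch1, ch2, roi = NULL,
                                channel_pair = c("ch1", "ch2")) {
  if (!identical(dim(ch1), dim(ch2)) || length(ch1) != length(ch2))
    stop_netquant("channels differ in shape", "netquant_dimension_error")
  a <- as.numeric(ch1)
  b <- as.numeric(ch2)
  if (!is.null(roi)) {
    r <- mask_raster(roi)
    if (length(r) != length(a))
      stop_netquant("ROI shape does not match channels",
                    "netquant_dimension_error")
    a <- a[as.logical(r)]
    b <- b[as.logical(r)]
  }
  if (length(a) == 0)
    stop_netquant("ROI selects no pixels", "netquant_parameter_error")
  ss1 <- sum(a^2)
  ss2 <- sum(b^2)
  if (ss1 == 0 || ss2 == 0)
    stop_netquant("overlap undefined: a channel is all zero within the ROI",
                  "netquant_undefined_result")
  structure(list(coefficient = sum(a * b) / sqrt(ss1 * ss2),
                 n_pixels = length(a), channel_pair = channel_pair),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("<overlap_result> %s-%s: R = %.4f over %d px\n",
              x$channel_pair[1], x$channel_pair[2], x$coefficient,
              x$n_pixels))
  invisible(x)
}
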