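#' Overlay rendering style
#'
#' @param color_map Named list mapping each class in use to an RGB triple
#'   in 0..255. Defaults: net = red, resting = cyan, unclassified = yellow.
#' @param line_width Boundary line width in pixels (>= 1; widths above 1
#'   dilate the boundary).
#' @param background Which channel to render underneath: `"dna"`,
#'   `"marker"`, or `"composite"` (pixelwise max of both).
#' @return List of class `overlay_style`.
#' @export
overlay_style <- function(color_map = list(net = c(255, 0, 0),
                                           resting = c(0, 255, 255),
                                           unclassified = c(255, 255, 0)),
                          line_width = 1L,
                          background = c("dna", "marker", "composite")) {
  if (line_width < 1)
    stop_netquant("line_width must be >= 1", "netquant_config_error")
  structure(list(color_map = color_map,
                 line_width = as.integer(line_width),
                 background = match.arg(background)),
            class = "overlay_style")
}

#' Render class-colored boundary overlays
#'
#' Draws each object's boundary, colored by its class, on top of a
#' contrast-stretched grayscale rendering of the chosen channel. Pixels
#' away from the (dilated) boundaries keep the grayscale value.
#'
#' @param field A [multichannel_field()].
#' @param records Object table carrying `class` and `boundary`.
#' @param style An [overlay_style()].
#' @return An `h x w x 3` integer array with values in 0..255.
#' @export
render_overlay <- function(field, records, style = overlay_style()) {
  bg <- switch(style$background,
               dna = field$dna,
               marker = field$marker,
               composite = pmax(field$dna, field$marker))
  g <- contrast_stretch(bg)
  out <- array(g, dim = c(dim(g), 3L))
  if (nrow(records) > 0) {
    if (is.null(records$boundary) ||
        any(vapply(records$boundary, is.null, logical(1))))
      stop_netquant("records carry no boundary coordinates",
                    "netquant_state_error")
    for (i in seq_len(nrow(records))) {
      cls <- records$class[i]
      col <- style$color_map[[cls]]
      if (is.null(col))
        stop_netquant(sprintf("no overlay color for class '%s'", cls),
                      "netquant_config_error")
      px <- dilate_points(records$boundary[[i]], style$line_width, dim(g))
      for (ch in 1:3)
        out[cbind(px[, 1] + 1L, px[, 2] + 1L, ch)] <- col[ch]
    }
  }
  storage.mode(out) <- "integer"
  out
}

# min-max stretch to 0..255; a flat image maps to 0
contrast_stretch <- function(img) {
  d <- dim(img)
  v <- as.numeric(img)
  lo <- min(v); hi <- max(v)
  s <- if (hi > lo) round(255 * (v - lo) / (hi - lo)) else v * 0
  matrix(as.integer(s), nrow = d[1], ncol = d[2])
}

# expand 0-based (row, col) points with a square brush of the given width,
# clipped to the image
dilate_points <- function(pts, width, dims) {
  r <- as.integer(width) - 1L
  if (r > 0) {
    off <- expand.grid(dr = -r:r, dc = -r:r)
    pts <- unique(cbind(rep(pts[, 1], each = nrow(off)) + off$dr,
                        rep(pts[, 2], each = nrow(off)) + off$dc))
  }
  keep <- pts[, 1] >= 0 & pts[, 1] < dims[1] &
    pts[, 2] >= 0 & pts[, 2] < dims[2]
  pts[keep, , drop = FALSE]
}

#' Write an RGB overlay array as a PNG file
#'
#' @param rgb `h x w x 3` array in 0..255 (from [render_overlay()]).
#' @param path Output path.
#' @export
write_overlay_png <- function(rgb, path) {
  png::writePNG(rgb / 255, path)
  invisible(path)
}
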