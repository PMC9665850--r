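#' Label connected foreground components
#'
#' Each maximal connected foreground component receives a distinct positive
#' label; background is 0. Labels are assigned deterministically in
#' raster-scan order (top-to-bottom, left-to-right) of each component's
#' first pixel.
#'
#' @param mask A [binary_mask()] or logical matrix.
#' @param connectivity 4 (edge neighbors) or 8 (edge + diagonal; the
#'   particle-analysis default).
#' @return Integer matrix of labels.
#' @export
label_components <- function(mask, connectivity = 8L) {
  raster <- mask_raster(mask)
  stopifnot(is.logical(raster), is.matrix(raster))
  if (!connectivity %in% c(4L, 8L))
    stop_netquant("connectivity must be 4 or 8", "netquant_config_error")
  cpp_label(raster, as.integer(connectivity))
}

#' Filter labeled objects by area
#'
#' Retains objects whose pixel count lies in `[min_area, max_area]`
#' (inclusive at both ends, matching particle-analysis size-range
#' semantics; the published gates such as "25-infinity" are read as
#' `[25, Inf)`). Rejected objects are relabeled to background; surviving
#' objects keep their original labels. Objects touching the image border
#' are retained.
#'
#' @param labels Integer label matrix from [label_components()].
#' @param min_area Minimum area in pixels^2 (>= 1).
#' @param max_area Maximum area in pixels^2, or `Inf`.
#' @return Filtered label matrix.
#' @export
particle_filter <- function(labels, min_area = 1L, max_area = Inf) {
  stopifnot(is.matrix(labels))
  if (min_area < 1)
    stop_netquant("min_area must be >= 1", "netquant_parameter_error")
  if (max_area < min_area)
    stop_netquant("max_area must be >= min_area", "netquant_parameter_error")
  if (max(labels) == 0L) return(labels)
  areas <- tabulate(labels[labels > 0L])
  keep <- which(areas >= min_area & areas <= max_area)
  out <- labels
  out[!(labels %in% keep)] <- 0L
  out
}

#' Measure segmented objects
#'
#' Computes, for every label, the area (pixel count), centroid (mean pixel
#' coordinate), ordered outer boundary, and the cumulative raw intensity of
#' each channel over the object's pixels. Coordinates are 0-based
#' `(row, col)` with the origin at the top-left pixel center; the boundary
#' is the object's 8-connected outer-boundary pixels ordered clockwise
#' starting from the topmost-then-leftmost boundary pixel.
#'
#' @param labels Integer label matrix.
#' @param field A [multichannel_field()] with rasters of the same shape.
#' @return A data frame with one row per object: `label`, `area`,
#'   `centroid_row`, `centroid_col`, `sum_dna`, `sum_marker`,
#'   `norm_marker_intensity` (NA until [normalize_timecourse()]), `class`
#'   (`"unclassified"` until [classify_objects()]), `field_id`, and a
#'   `boundary` list column of n x 2 integer matrices.
#' @export
measure_objects <- function(labels, field) {
  if (!identical(dim(labels), dim(field$dna)))
    stop_netquant("label matrix and field rasters differ in shape",
                  "netquant_dimension_error")
  ids <- sort(unique(labels[labels > 0L]))
  if (length(ids) == 0L) return(empty_object_table())
  idx <- which(labels > 0L)
  lab <- labels[idx]
  rows0 <- (idx - 1L) %% nrow(labels)        # 0-based row
  cols0 <- (idx - 1L) %/% nrow(labels)       # 0-based col
  area <- as.integer(tapply(rep(1L, length(idx)), lab, sum)[as.character(ids)])
  cr <- as.numeric(tapply(rows0, lab, mean)[as.character(ids)])
  cc <- as.numeric(tapply(cols0, lab, mean)[as.character(ids)])
  sd_ <- as.numeric(tapply(as.numeric(field$dna[idx]), lab,
                           sum)[as.character(ids)])
  sm <- as.numeric(tapply(as.numeric(field$marker[idx]), lab,
                          sum)[as.character(ids)])
  boundary <- lapply(ids, function(id) trace_boundary(labels == id))
  out <- data.frame(label = ids, area = area, centroid_row = cr,
                    centroid_col = cc, sum_dna = sd_, sum_marker = sm,
                    norm_marker_intensity = NA_real_,
                    class = "unclassified", field_id = field$field_id,
                    stringsAsFactors = FALSE)
  out$boundary <- boundary
  out
}

empty_object_table <- function() {
  out <- data.frame(label = integer(0), area = integer(0),
                    centroid_row = numeric(0), centroid_col = numeric(0),
                    sum_dna = numeric(0), sum_marker = numeric(0),
                    norm_marker_intensity = numeric(0),
                    class = character(0), field_id = character(0),
                    stringsAsFactors = FALSE)
  out$boundary <- list()
  out
}

# Moore-neighbor boundary trace of a single object (logical matrix).
# Returns the object's 8-connected outer-boundary pixels as an n x 2
# matrix of 0-based (row, col), ordered clockwise (in display coordinates,
# row increasing downward) from the topmost-then-leftmost pixel. Pixels
# revisited by the trace (single-pixel-wide arms) are reported once, at
# their first visit.
trace_boundary <- function(obj) {
  nr <- nrow(obj); nc <- ncol(obj)
  idx <- which(obj)
  if (length(idx) == 0L)
    stop_netquant("cannot trace an empty object", "netquant_state_error")
  rows <- (idx - 1L) %% nr
  cols <- (idx - 1L) %/% nr
  r0 <- min(rows)
  c0 <- min(cols[rows == r0])
  if (length(idx) == 1L)
    return(matrix(c(r0, c0), ncol = 2,
                  dimnames = list(NULL, c("row", "col"))))
  # clockwise directions: N, NE, E, SE, S, SW, W, NW
  dr <- c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L)
  dc <- c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L)
  inside <- function(r, c) r >= 0L && r < nr && c >= 0L && c < nc &&
    obj[r + 1L, c + 1L]
  path_r <- integer(0); path_c <- integer(0)
  p <- c(r0, c0)
  back_dir <- 7L   # entered "from the west" (index of W)
  start_state <- c(p, back_dir)
  repeat {
    path_r <- c(path_r, p[1]); path_c <- c(path_c, p[2])
    found <- FALSE
    for (k in seq_len(8L)) {
      d <- ((back_dir + k - 1L) %% 8L) + 1L   # scan clockwise after backtrack
      rr <- p[1] + dr[d]; cc <- p[2] + dc[d]
      if (inside(rr, cc)) {
        # new backtrack: the neighbor checked just before this one
        back_dir <- ((d - 2L) %% 8L) + 1L
        # re-express backtrack as seen from the NEW pixel: direction from
        # new pixel to the previously checked (background) neighbor
        prev_bg <- c(p[1] + dr[back_dir], p[2] + dc[back_dir])
        p <- c(rr, cc)
        rel <- prev_bg - p
        back_dir <- which(dr == rel[1] & dc == rel[2])
        found <- TRUE
        break
      }
    }
    if (!found) break   # isolated pixel (cannot happen for area > 1)
    if (identical(c(p, back_dir), start_state)) break
    if (length(path_r) > 4L * length(idx) + 8L) break  # safety cap
  }
  pts <- cbind(row = path_r, col = path_c)
  pts[!duplicated(pts), , drop = FALSE]
}
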