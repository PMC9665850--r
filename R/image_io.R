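#' Construct a two-channel field
#'
#' Bundles a registered pair of single-plane intensity rasters (DNA stain
#' and antibody marker) with the acquisition metadata the pipeline needs:
#' field id, time point, stimulus, objective magnification and bit depth.
#'
#' @param dna,marker Integer matrices of identical dimensions; intensities
#'   in `[0, 2^bit_depth - 1]`.
#' @param field_id Character scalar identifying the field of view.
#' @param time_point_min Non-negative time point in minutes.
#' @param stimulus Character label of the stimulus.
#' @param objective `"10x"` or `"20x"` (the two magnifications for which
#'   particle-size gates are defined).
#' @param bit_depth 8 or 16.
#' @return An object of class `multichannel_field` (a list with the fields
#'   above).
#' @export
multichannel_field <- function(dna, marker, field_id = "field",
                               time_point_min = 0, stimulus = "none",
                               objective = c("20x", "10x"), bit_depth = 8L) {
  objective <- match.arg(objective)
  dna <- as_intensity_matrix(dna)
  marker <- as_intensity_matrix(marker)
  if (!identical(dim(dna), dim(marker)))
    stop_netquant("dna and marker rasters must have identical dimensions",
                  "netquant_dimension_error")
  bit_depth <- as.integer(bit_depth)
  if (!bit_depth %in% c(8L, 16L))
    stop_netquant("bit_depth must be 8 or 16", "netquant_format_error")
  top <- 2^bit_depth - 1
  rng <- range(dna, marker)
  if (rng[1] < 0 || rng[2] > top)
    stop_netquant(sprintf("intensities must lie in [0, %d]", top),
                  "netquant_format_error")
  if (time_point_min < 0)
    stop_netquant("time_point_min must be non-negative",
                  "netquant_config_error")
  structure(list(dna = dna, marker = marker,
                 field_id = as.character(field_id),
                 time_point_min = as.numeric(time_point_min),
                 stimulus = as.character(stimulus),
                 objective = objective, bit_depth = bit_depth),
            class = "multichannel_field")
}

#' @export
print.multichannel_field <- function(x, ...) {
  cat(sprintf(
    "<multichannel_field> %s: %dx%d px, %d-bit, %s, t=%g min, stimulus=%s\n",
    x$field_id, nrow(x$dna), ncol(x$dna), x$bit_depth, x$objective,
    x$time_point_min, x$stimulus))
  invisible(x)
}

as_intensity_matrix <- function(x) {
  if (!is.matrix(x))
    stop_netquant("channel raster must be a 2-D matrix",
                  "netquant_format_error")
  if (is.double(x)) {
    if (any(x != floor(x)))
      stop_netquant("channel raster must be integer-valued",
                    "netquant_format_error")
    storage.mode(x) <- "integer"
  }
  if (!is.integer(x))
    stop_netquant("channel raster must be integer-valued",
                  "netquant_format_error")
  x
}

# Read one grayscale TIFF into a list of integer matrices (one per plane)
# plus the bits-per-sample. Rejects RGB/multi-sample and floating-point
# sample formats.
read_gray_tiff <- function(path) {
  if (!file.exists(path))
    stop_netquant(paste("file not found:", path), "netquant_io_error")
  planes <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
  planes <- lapply(planes, function(p) {
    bits <- attr(p, "bits.per.sample")
    fmt <- attr(p, "sample.format")
    if (!is.null(fmt) && !identical(fmt, "uint"))
      stop_netquant(paste("unsupported TIFF sample format:", fmt),
                    "netquant_format_error")
    if (length(dim(p)) != 2L)
      stop_netquant("TIFF must be single-sample grayscale (not RGB/RGBA)",
                    "netquant_format_error")
    if (is.double(p) && all(p >= 0) && all(p <= 1) && any(p != floor(p)))
      stop_netquant("floating-point TIFFs are not supported",
                    "netquant_format_error")
    p <- matrix(as.integer(p), nrow(p), ncol(p))  # drop TIFF info attrs
    attr(p, "bits") <- if (is.null(bits)) 8L else as.integer(bits)
    p
  })
  planes
}

#' Read a two-channel field from a pair of grayscale TIFF files
#'
#' Both files must be single-plane grayscale TIFFs (8- or 16-bit unsigned
#' integer) of identical shape. Bit depth is inferred from the files. For
#' multi-page stacks see [read_field_stack()].
#'
#' @param path_dna,path_marker Paths to the DNA-stain and marker TIFFs.
#' @param metadata Named list with optional `field_id`, `time_point_min`,
#'   `stimulus`, `objective`.
#' @return A [multichannel_field()].
#' @export
read_field <- function(path_dna, path_marker, metadata = list()) {
  d <- read_gray_tiff(path_dna)
  m <- read_gray_tiff(path_marker)
  if (length(d) != 1L || length(m) != 1L)
    stop_netquant(
      "multi-page TIFF passed to read_field(); use read_field_stack()",
      "netquant_format_error")
  build_field_from_planes(d[[1]], m[[1]], metadata)
}

build_field_from_planes <- function(dna, marker, metadata) {
  if (!identical(dim(dna), dim(marker)))
    stop_netquant("dna and marker TIFFs differ in shape",
                  "netquant_dimension_error")
  bits <- max(attr(dna, "bits"), attr(marker, "bits"))
  if (!bits %in% c(8L, 16L))
    stop_netquant(sprintf("unsupported bit depth %d", bits),
                  "netquant_format_error")
  attr(dna, "bits") <- NULL
  attr(marker, "bits") <- NULL
  multichannel_field(
    dna, marker,
    field_id = metadata$field_id %||% "field",
    time_point_min = metadata$time_point_min %||% 0,
    stimulus = metadata$stimulus %||% "none",
    objective = metadata$objective %||% "20x",
    bit_depth = bits)
}

#' Read a multi-page TIFF pair as a list of per-plane fields
#'
#' Pages are split in file order; each plane becomes its own field whose id
#' is the base `field_id` suffixed with `_pN`.
#'
#' @inheritParams read_field
#' @return A list of [multichannel_field()] objects.
#' @export
read_field_stack <- function(path_dna, path_marker, metadata = list()) {
  d <- read_gray_tiff(path_dna)
  m <- read_gray_tiff(path_marker)
  if (length(d) != length(m))
    stop_netquant("dna and marker stacks have different page counts",
                  "netquant_dimension_error")
  base_id <- metadata$field_id %||% "field"
  lapply(seq_along(d), function(i) {
    md <- metadata
    md$field_id <- sprintf("%s_p%d", base_id, i)
    build_field_from_planes(d[[i]], m[[i]], md)
  })
}

#' Write an integer raster as a grayscale TIFF
#'
#' The written file round-trips bit-exactly through [read_field()].
#'
#' @param img Integer matrix with values in `[0, 2^bit_depth - 1]`.
#' @param path Output path.
#' @param bit_depth 8 or 16.
#' @export
write_gray_tiff <- function(img, path, bit_depth = 8L) {
  img <- as_intensity_matrix(img)
  top <- 2^bit_depth - 1
  if (min(img) < 0 || max(img) > top)
    stop_netquant("intensities out of range for the requested bit depth",
                  "netquant_format_error")
  tiff::writeTIFF(img / top, path, bits.per.sample = as.integer(bit_depth))
  invisible(path)
}

#' Particle-size gates for an objective magnification
#'
#' Returns the minimum particle areas (pixels^2) used by the counting
#' pipeline: `min_area_total` gates objects counted as cells on the DNA
#' channel, `min_area_net` gates objects counted as NETs on the marker
#' channel (a NET is larger than a resting cell nucleus). The 10x gates are
#' 25 / 75 and the 20x gates 100 / 250.
#'
#' @param objective `"10x"` or `"20x"`.
#' @return Named list with `min_area_total` and `min_area_net`.
#' @export
resolve_size_gates <- function(objective) {
  gates <- list(`10x` = list(min_area_total = 25L, min_area_net = 75L),
                `20x` = list(min_area_total = 100L, min_area_net = 250L))
  if (length(objective) != 1L || !objective %in% names(gates))
    stop_netquant(sprintf(
      "no size gates defined for objective '%s' (use 10x or 20x)",
      paste(objective, collapse = ",")), "netquant_config_error")
  gates[[objective]]
}

#' Build a run configuration
#'
#' Collects every tunable of the counting pipeline. Size gates are resolved
#' from the objective unless overridden; `mode = "manual"` requires a
#' marker threshold.
#'
#' @param mode `"auto"` (Bernsen local threshold on both channels) or
#'   `"manual"` (global threshold on the marker channel).
#' @param objective `"10x"` or `"20x"`; sets the default size gates.
#' @param bernsen_radius Neighborhood radius in pixels (default 15).
#' @param bernsen_contrast Local-contrast parameter in intensity units
#'   (default 35).
#' @param manual_threshold_marker,manual_threshold_dna Global intensity
#'   cutoffs for manual mode (`NULL` if unused; only the marker threshold is
#'   required, the DNA channel is always thresholded automatically).
#' @param min_area_total,min_area_net,max_area Particle-size gates in
#'   pixels^2; `max_area = Inf` disables the upper gate.
#' @param min_quality Quality-score exclusion cutoff in `[0, 1]`.
#' @param connectivity 4 or 8 (default 8, the particle-analysis convention).
#' @param intensity_min_net Normalized-intensity cutoff used by
#'   [classify_objects()].
#' @param seed Optional integer seed recorded in run reports.
#' @return A list of class `run_config` with all fields resolved.
#' @export
run_config <- function(mode = c("auto", "manual"),
                       objective = c("20x", "10x"),
                       bernsen_radius = 15L, bernsen_contrast = 35,
                       manual_threshold_marker = NULL,
                       manual_threshold_dna = NULL,
                       min_area_total = NULL, min_area_net = NULL,
                       max_area = Inf, min_quality = 0.5,
                       connectivity = 8L, intensity_min_net = 0.3,
                       seed = NULL) {
  mode <- match.arg(mode)
  objective <- match.arg(objective)
  gates <- resolve_size_gates(objective)
  min_area_total <- min_area_total %||% gates$min_area_total
  min_area_net <- min_area_net %||% gates$min_area_net
  if (min_area_net < min_area_total)
    stop_netquant("min_area_net must be >= min_area_total",
                  "netquant_config_error")
  if (mode == "manual" && is.null(manual_threshold_marker))
    stop_netquant("manual mode requires manual_threshold_marker",
                  "netquant_config_error")
  if (bernsen_radius < 1)
    stop_netquant("bernsen_radius must be >= 1", "netquant_config_error")
  if (bernsen_contrast < 0)
    stop_netquant("bernsen_contrast must be >= 0", "netquant_config_error")
  if (min_quality < 0 || min_quality > 1)
    stop_netquant("min_quality must be in [0, 1]", "netquant_config_error")
  if (!connectivity %in% c(4L, 8L))
    stop_netquant("connectivity must be 4 or 8", "netquant_config_error")
  structure(list(
    mode = mode, objective = objective,
    bernsen_radius = as.integer(bernsen_radius),
    bernsen_contrast = as.numeric(bernsen_contrast),
    manual_threshold_marker = manual_threshold_marker,
    manual_threshold_dna = manual_threshold_dna,
    min_area_total = as.integer(min_area_total),
    min_area_net = as.integer(min_area_net),
    max_area = max_area, min_quality = as.numeric(min_quality),
    connectivity = as.integer(connectivity),
    intensity_min_net = as.numeric(intensity_min_net),
    seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "run_config")
}

#' Read a run configuration from a JSON file
#'
#' The JSON mirrors the arguments of [run_config()]; absent keys take the
#' built-in defaults. `"max_area": null` or `"Inf"` both mean unbounded.
#'
#' @param path Path to the JSON configuration.
#' @param overrides Named list applied on top of the file (CLI precedence:
#'   flag > file > default).
#' @return A `run_config`.
#' @export
read_run_config <- function(path, overrides = list()) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- utils::modifyList(cfg, overrides[!vapply(overrides, is.null,
                                                  logical(1))])
  if (!is.null(cfg$max_area) && is.character(cfg$max_area))
    cfg$max_area <- as.numeric(cfg$max_area)
  if (is.null(cfg$max_area)) cfg$max_area <- Inf
  known <- names(formals(run_config))
  do.call(run_config, cfg[intersect(names(cfg), known)])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write the per-object result table
#'
#' Writes one CSV row per segmented object (label, field id, area in
#' pixels^2, centroid as x = column / y = row in 0-based pixel coordinates,
#' cumulative intensity per channel, class) and a sidecar JSON next to the
#' CSV holding each object's ordered boundary coordinate list (0-based
#' `[row, col]` pairs, clockwise from the topmost-then-leftmost boundary
#' pixel).
#'
#' @param records Object table from [measure_objects()] (rows from several
#'   fields may be concatenated; a `field_id` column is added if missing).
#' @param path Output CSV path; the sidecar is `<path>_boundaries.json`.
#' @return `path`, invisibly.
#' @export
write_object_table <- function(records, path) {
  cols <- c("label", "field_id", "area_px", "centroid_x", "centroid_y",
            "sum_dna", "sum_marker", "class")
  if (nrow(records) == 0) {
    tab <- as.data.frame(stats::setNames(
      rep(list(numeric(0)), length(cols)), cols))
    boundaries <- stats::setNames(list(), character(0))
  } else {
    if (is.null(records$field_id)) records$field_id <- "field"
    tab <- data.frame(label = records$label, field_id = records$field_id,
                      area_px = records$area,
                      centroid_x = records$centroid_col,
                      centroid_y = records$centroid_row,
                      sum_dna = records$sum_dna,
                      sum_marker = records$sum_marker,
                      class = records$class)
    boundaries <- stats::setNames(
      lapply(records$boundary, function(b) unname(apply(b, 1, c,
                                                        simplify = FALSE))),
      paste(records$field_id, records$label, sep = "/"))
  }
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(boundaries, paste0(path, "_boundaries.json"),
                       auto_unbox = FALSE)
  invisible(path)
}

#' Write the per-field result table
#'
#' One CSV row per field of view: counts, percentage of NETs, quality score
#' and the exclusion flag.
#'
#' @param results Data frame of field results (from [quantify_field()] rows
#'   bound together, or [quantify_fields()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_field_table <- function(results, path) {
  cols <- c("field_id", "time_point_min", "stimulus", "method", "n_total",
            "n_net", "percent_net", "quality_score", "excluded")
  if (nrow(results) == 0) {
    results <- as.data.frame(stats::setNames(
      rep(list(numeric(0)), length(cols)), cols))
  }
  utils::write.csv(results[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
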