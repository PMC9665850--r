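#' Count total cells on the DNA channel
#'
#' Totals are always counted automatically, in both regimes: the DNA
#' channel is binarized with the Bernsen local threshold, connected
#' components are labeled, and the total-cell size gate
#' (`min_area_total`, resolved from the objective) is applied.
#'
#' @param field A [multichannel_field()].
#' @param config A [run_config()].
#' @return List with `count`, the filtered `labels` matrix, and the DNA
#'   `mask`.
#' @export
count_total <- function(field, config) {
  mask <- bernsen_threshold(field$dna, config$bernsen_radius,
                            config$bernsen_contrast, field$bit_depth)
  mask$source_channel <- "dna"
  labs <- label_components(mask, config$connectivity)
  labs <- particle_filter(labs, config$min_area_total, config$max_area)
  list(count = n_objects(labs), labels = labs, mask = mask)
}

#' Count NETs on the marker channel
#'
#' In the automatic regime the marker channel is binarized with the same
#' Bernsen local threshold as the DNA channel; in the manual regime a fixed
#' global cutoff (`manual_threshold_marker`) is used, set so that the
#' weaker staining of resting nuclei is excluded. Components are then
#' labeled and the NET size gate (`min_area_net`; a NET is larger than a
#' resting cell nucleus) is applied.
#'
#' @inheritParams count_total
#' @return List with `count`, the filtered `labels` matrix, and the marker
#'   `mask`.
#' @export
count_nets <- function(field, config) {
  if (config$mode == "manual") {
    if (is.null(config$manual_threshold_marker))
      stop_netquant("manual mode requires manual_threshold_marker",
                    "netquant_config_error")
    mask <- global_threshold(field$marker, config$manual_threshold_marker)
  } else {
    mask <- bernsen_threshold(field$marker, config$bernsen_radius,
                              config$bernsen_contrast, field$bit_depth)
  }
  mask$source_channel <- "marker"
  labs <- label_components(mask, config$connectivity)
  labs <- particle_filter(labs, config$min_area_net, config$max_area)
  list(count = n_objects(labs), labels = labs, mask = mask)
}

n_objects <- function(labels) length(unique(labels[labels > 0L]))

#' Percentage of NETs
#'
#' `percent_net = 100 * n_net / n_total`. A field with zero total cells has
#' no defined percentage and must be excluded upstream. The value may
#' exceed 100 when NET structures fragment differently across the two
#' channels; this is flagged with a warning, never clamped.
#'
#' @param n_net,n_total Non-negative object counts.
#' @return The percentage as a number.
#' @export
percent_nets <- function(n_net, n_total) {
  if (n_net < 0 || n_total < 0)
    stop_netquant("counts must be non-negative", "netquant_parameter_error")
  if (n_total == 0)
    stop_netquant("percent NETs is undefined for n_total = 0 (exclude field)",
                  "netquant_undefined_result")
  p <- 100 * n_net / n_total
  if (p > 100)
    warning(sprintf("percent_net %.1f exceeds 100 (n_net %d > n_total %d)",
                    p, n_net, n_total))
  p
}

#' Quantify a single field of view
#'
#' Runs the full counting pipeline on one field: automatic total-cell count
#' on the DNA channel, NET count on the marker channel under the configured
#' regime, quality score against the total-cell labeling, and the
#' percentage of NETs. Fields with no accepted total objects get
#' `percent_net = NA` and are excluded.
#'
#' @param field A [multichannel_field()].
#' @param config A [run_config()].
#' @return List with `result` (one-row field table), `objects` (the
#'   measured object table of the total-cell segmentation), `quality`,
#'   `total` and `nets` (the two count structures).
#' @export
quantify_field <- function(field, config) {
  tot <- count_total(field, config)
  net <- count_nets(field, config)
  q <- quality_score(tot$mask, tot$labels, field$field_id,
                     config$min_quality)
  pct <- if (tot$count > 0) percent_nets(net$count, tot$count) else NA_real_
  excluded <- q$excluded || tot$count == 0
  objects <- measure_objects(tot$labels, field)
  result <- data.frame(
    field_id = field$field_id, time_point_min = field$time_point_min,
    stimulus = field$stimulus, method = config$mode,
    n_total = tot$count, n_net = net$count, percent_net = pct,
    quality_score = q$score, excluded = excluded,
    stringsAsFactors = FALSE)
  list(result = result, objects = objects, quality = q, total = tot,
       nets = net)
}

#' Quantify a list of fields
#'
#' @param fields List of [multichannel_field()] objects.
#' @param config A [run_config()].
#' @return List with `results` (field table, one row per field) and
#'   `objects` (concatenated object tables).
#' @export
quantify_fields <- function(fields, config) {
  per <- lapply(fields, quantify_field, config = config)
  results <- do.call(rbind, lapply(per, `[[`, "result"))
  objects <- do.call(rbind, lapply(per, `[[`, "objects"))
  list(results = results, objects = objects)
}

#' Normalize marker intensities over a time course
#'
#' Each object's mean marker intensity (`sum_marker / area`) is divided by
#' the maximum per-object mean over ALL fields and time points of the
#' series (series-wide, not per-image), giving values in `(0, 1]` with at
#' least one object exactly 1.
#'
#' @param records Object table (possibly concatenated over many fields).
#' @return The records with `norm_marker_intensity` filled in.
#' @export
normalize_timecourse <- function(records) {
  if (nrow(records) == 0) return(records)
  means <- records$sum_marker / records$area
  top <- max(means)
  if (top <= 0)
    stop_netquant("cannot normalize an all-zero marker series",
                  "netquant_degenerate_normalization")
  records$norm_marker_intensity <- means / top
  records
}

#' Classification rule for objects
#'
#' An object is a NET when it is at least as large as the NET area gate AND
#' its normalized marker intensity reaches the intensity cutoff; otherwise
#' it is resting. Ties at either threshold classify as NET.
#'
#' @param objective `"10x"` or `"20x"`; sets the default area gate to the
#'   NET size gate of that magnification.
#' @param area_min_net Area gate in pixels^2 (default from
#'   [resolve_size_gates()]).
#' @param intensity_min_net Normalized-intensity gate in `[0, 1]`
#'   (default 0.3).
#' @return List of class `classification_rule`.
#' @export
classification_rule <- function(objective = "20x", area_min_net = NULL,
                                intensity_min_net = 0.3) {
  area_min_net <- area_min_net %||%
    resolve_size_gates(objective)$min_area_net
  if (area_min_net < 0 || intensity_min_net < 0)
    stop_netquant("classification thresholds must be >= 0",
                  "netquant_config_error")
  structure(list(area_min_net = area_min_net,
                 intensity_min_net = intensity_min_net),
            class = "classification_rule")
}

#' Classify objects by area and normalized staining intensity
#'
#' @param records Object table with `norm_marker_intensity` present (run
#'   [normalize_timecourse()] first).
#' @param rule A [classification_rule()].
#' @return The records with `class` set to `"net"` or `"resting"`.
#' @export
classify_objects <- function(records, rule = classification_rule()) {
  if (nrow(records) == 0) return(records)
  if (anyNA(records$norm_marker_intensity))
    stop_netquant(
      "norm_marker_intensity missing; run normalize_timecourse() first",
      "netquant_state_error")
  is_net <- records$area >= rule$area_min_net &
    records$norm_marker_intensity >= rule$intensity_min_net
  records$class <- ifelse(is_net, "net", "resting")
  records
}

#' Aggregate field results per sample
#'
#' Averages `percent_net` over the fields of view of each group (e.g. one
#' stimulus at one time point), after dropping excluded fields. Groups with
#' no usable field are omitted with a warning.
#'
#' @param results Field table.
#' @param group_by Character vector of grouping columns.
#' @return Data frame with the group keys plus `mean_percent_net`,
#'   `sd_percent_net` (0 for a single field) and `n_fov`.
#' @export
aggregate_fields <- function(results,
                             group_by = c("stimulus", "time_point_min",
                                          "method")) {
  all_keys <- unique(results[, group_by, drop = FALSE])
  use <- results[!results$excluded & !is.na(results$percent_net), ,
                 drop = FALSE]
  if (nrow(use) < nrow(results) || nrow(use) == 0) {
    kept <- unique(use[, group_by, drop = FALSE])
    lost <- nrow(all_keys) - nrow(merge(all_keys, kept))
    if (lost > 0)
      warning(sprintf("%d group(s) omitted: all fields excluded", lost))
  }
  if (nrow(use) == 0)
    return(cbind(all_keys[0, , drop = FALSE],
                 mean_percent_net = numeric(0),
                 sd_percent_net = numeric(0), n_fov = integer(0)))
  key <- interaction(use[, group_by, drop = FALSE], drop = TRUE)
  agg <- do.call(rbind, lapply(split(use, key), function(g) {
    cbind(g[1, group_by, drop = FALSE],
          mean_percent_net = mean(g$percent_net),
          sd_percent_net = if (nrow(g) > 1) stats::sd(g$percent_net) else 0,
          n_fov = nrow(g))
  }))
  rownames(agg) <- NULL
  agg
}

#' Run both regimes on the same fields and pair the results
#'
#' @param fields List of [multichannel_field()] objects.
#' @param config A [run_config()]; `manual_threshold_marker` must be set.
#' @return Data frame with `field_id`, `percent_net_manual`,
#'   `percent_net_auto`.
#' @export
compare_methods <- function(fields, config) {
  cfg_manual <- config; cfg_manual$mode <- "manual"
  if (is.null(cfg_manual$manual_threshold_marker))
    stop_netquant("compare_methods requires manual_threshold_marker",
                  "netquant_config_error")
  cfg_auto <- config; cfg_auto$mode <- "auto"
  man <- quantify_fields(fields, cfg_manual)$results
  aut <- quantify_fields(fields, cfg_auto)$results
  data.frame(field_id = man$field_id,
             percent_net_manual = man$percent_net,
             percent_net_auto = aut$percent_net,
             stringsAsFactors = FALSE)
}
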