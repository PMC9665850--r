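#' Per-image quality score
#'
#' The quality score of a field is the fraction of the total DNA-stained
#' area (foreground of the DNA mask) that is covered by objects accepted as
#' individual cells or NETs (nonzero labels in the post-filter labeling of
#' that mask). A field with no DNA foreground at all gets score 0 and a
#' degenerate flag.
#'
#' @param dna_mask [binary_mask()] (or logical matrix) of the DNA channel.
#' @param accepted Integer label matrix after [particle_filter()], computed
#'   from `dna_mask`.
#' @param field_id Field identifier carried into the report.
#' @param min_quality Exclusion cutoff in `[0, 1]`.
#' @return A one-row data frame: `field_id`, `dna_area`, `assigned_area`,
#'   `score`, `excluded`, `min_quality`, `degenerate`.
#' @export
quality_score <- function(dna_mask, accepted, field_id = "field",
                          min_quality = 0.5) {
  raster <- mask_raster(dna_mask)
  if (!identical(dim(raster), dim(accepted)))
    stop_netquant("mask and labeling differ in shape",
                  "netquant_dimension_error")
  dna_area <- sum(raster)
  assigned <- sum(raster & accepted > 0L)
  degenerate <- dna_area == 0L
  score <- if (degenerate) 0 else assigned / dna_area
  data.frame(field_id = field_id, dna_area = dna_area,
             assigned_area = assigned, score = score,
             excluded = score < min_quality, min_quality = min_quality,
             degenerate = degenerate, stringsAsFactors = FALSE)
}

#' Apply a quality-score exclusion cutoff
#'
#' Re-evaluates the `excluded` flag of each report against `min_quality`.
#' No report is removed: exclusion is a flag consumed by downstream
#' aggregation, so excluded fields remain auditable.
#'
#' @param reports Data frame of quality reports (rows from
#'   [quality_score()]).
#' @param min_quality Cutoff in `[0, 1]`; fields with `score < min_quality`
#'   are flagged.
#' @return The reports with `excluded` and `min_quality` updated.
#' @export
apply_exclusion <- function(reports, min_quality) {
  if (min_quality < 0 || min_quality > 1)
    stop_netquant("min_quality must be in [0, 1]", "netquant_config_error")
  reports$excluded <- reports$score < min_quality
  reports$min_quality <- min_quality
  reports
}
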