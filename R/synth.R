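#' Staining model for synthetic fields
#'
#' Intensity model used by [generate_field()]. Two presets mirror the two
#' antibody behaviors the pipeline must distinguish:
#' \describe{
#'   \item{`d3d9_like`}{the marker stains decondensed (NET) chromatin almost
#'     exclusively; resting and spread nuclei show only background in the
#'     marker channel.}
#'   \item{`chromatin_like`}{a pan-chromatin stain: resting nuclei stain
#'     weakly, spread nuclei stain weakly and diffusely, NETs stain
#'     strongly — so every nucleus has marker signal above background.}
#' }
#' Channels are rendered as per-class mean intensities plus additive
#' Gaussian noise, clipped to the bit depth. All means are absolute
#' intensity levels (the background has its own mean).
#'
#' @param name `"d3d9_like"` or `"chromatin_like"`.
#' @param bit_depth 8 or 16 (defaults scale with bit depth).
#' @param noise_sd Gaussian noise standard deviation (intensity units).
#' @param background_mean Background intensity level.
#' @param dna_mean,marker_mean Named numeric vectors with entries
#'   `resting`, `spread`, `net` (absolute mean intensity of object pixels
#'   in each channel; values at or below `background_mean` mean unstained).
#' @return List of class `stain_model`.
#' @export
stain_model <- function(name = c("d3d9_like", "chromatin_like"),
                        bit_depth = 8L, noise_sd = NULL,
                        background_mean = NULL, dna_mean = NULL,
                        marker_mean = NULL) {
  name <- match.arg(name)
  bit_depth <- as.integer(bit_depth)
  k <- 2^(bit_depth - 8L)   # scale 8-bit defaults up for 16-bit
  noise_sd <- noise_sd %||% (3 * k)
  background_mean <- background_mean %||% (10 * k)
  dna_mean <- dna_mean %||%
    c(resting = 200, spread = 150, net = 170) * k
  marker_mean <- marker_mean %||% switch(
    name,
    d3d9_like = c(resting = 0, spread = 0, net = 200) * k,
    chromatin_like = c(resting = 90, spread = 90, net = 200) * k)
  top <- 2^bit_depth - 1
  if (any(c(dna_mean, marker_mean, background_mean) > top))
    stop_netquant("stain means exceed the bit-depth range",
                  "netquant_config_error")
  if (noise_sd < 0)
    stop_netquant("noise_sd must be >= 0", "netquant_config_error")
  structure(list(name = name, bit_depth = bit_depth, noise_sd = noise_sd,
                 background_mean = background_mean, dna_mean = dna_mean,
                 marker_mean = marker_mean),
            class = "stain_model")
}

# --- footprint construction -------------------------------------------------

# union of k overlapping ellipses on a local grid (lobulated nucleus)
lobed_footprint <- function(target_area) {
  k <- sample(2:5, 1)
  r <- sqrt(target_area / pi)
  half <- ceiling(3 * r) + 2
  n <- 2 * half + 1
  y <- matrix(rep(-half:half, n), n, n)
  x <- t(y)
  scale <- 1
  for (i in 1:12) {
    m <- matrix(FALSE, n, n)
    if (i == 1) {
      cx <- stats::runif(k, -0.55 * r, 0.55 * r)
      cy <- stats::runif(k, -0.55 * r, 0.55 * r)
      ax <- stats::runif(k, 0.55 * r, 0.8 * r)
      ay <- stats::runif(k, 0.55 * r, 0.8 * r)
    }
    for (j in 1:k)
      m <- m | (((x - cx[j] * scale) / (ax[j] * scale))^2 +
                  ((y - cy[j] * scale) / (ay[j] * scale))^2 <= 1)
    a <- sum(m)
    if (abs(a - target_area) / target_area < 0.12) return(trim_footprint(m))
    scale <- scale * sqrt(target_area / a)
  }
  trim_footprint(m)
}

# Gaussian-blurred super-ellipse (diffuse NET blob)
net_footprint <- function(target_area) {
  r <- sqrt(target_area / pi)
  half <- ceiling(2.2 * r) + 6
  n <- 2 * half + 1
  y <- matrix(rep(-half:half, n), n, n)
  x <- t(y)
  stretch <- stats::runif(1, 0.7, 1.4)
  theta <- stats::runif(1, 0, pi)
  xr <- cos(theta) * x + sin(theta) * y
  yr <- -sin(theta) * x + cos(theta) * y
  scale <- 1
  for (i in 1:12) {
    a <- r * stretch * scale
    b <- r / stretch * scale
    core <- (abs(xr / a)^3 + abs(yr / b)^3) <= 1
    sm <- gauss_blur(core * 1, sd = 2)
    m <- sm > 0.4
    ar <- sum(m)
    if (abs(ar - target_area) / target_area < 0.12) return(trim_footprint(m))
    scale <- scale * sqrt(target_area / ar)
  }
  trim_footprint(m)
}

# separable Gaussian blur with zero padding (small local grids only)
gauss_blur <- function(m, sd) {
  half <- ceiling(3 * sd)
  k <- stats::dnorm(-half:half, sd = sd)
  k <- k / sum(k)
  out <- matrix(0, nrow(m), ncol(m))
  for (i in seq_along(k)) {   # blur along rows
    s <- (-half:half)[i]
    rs <- max(1, 1 - s):min(nrow(m), nrow(m) - s)
    out[rs, ] <- out[rs, ] + k[i] * m[rs + s, ]
  }
  out2 <- matrix(0, nrow(m), ncol(m))
  for (i in seq_along(k)) {   # blur along cols
    s <- (-half:half)[i]
    cs <- max(1, 1 - s):min(ncol(m), ncol(m) - s)
    out2[, cs] <- out2[, cs] + k[i] * out[, cs + s]
  }
  out2
}

trim_footprint <- function(m) {
  rr <- range(which(rowSums(m) > 0))
  cc <- range(which(colSums(m) > 0))
  m[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
}

# area bands per class, derived from the objective's size gates so planted
# objects respect the gate semantics (resting strictly below the NET gate,
# NETs at least twice it)
class_area_band <- function(class, gates) {
  switch(class,
         resting = c(1.3 * gates$min_area_total, 0.85 * gates$min_area_net),
         spread = c(1.1 * gates$min_area_net, 1.6 * gates$min_area_net),
         net = c(2.2 * gates$min_area_net, 3.5 * gates$min_area_net))
}

class_area_ok <- function(class, area, gates) {
  switch(class,
         resting = area >= gates$min_area_total &&
           area < gates$min_area_net,
         spread = area >= gates$min_area_net,
         net = area >= 2 * gates$min_area_net)
}

#' Generate a synthetic two-channel field with ground truth
#'
#' Places non-overlapping nucleus footprints of three classes on an empty
#' field and renders both channels under a [stain_model()]:
#' \describe{
#'   \item{resting}{small multi-lobed nuclei, area within the total-cell
#'     gate but strictly below the NET gate;}
#'   \item{spread}{lobulated nuclei at least as large as the NET gate but
#'     with weak, diffuse DNA and chromatin-marker staining (the
#'     early-time-point confounder for pan-chromatin markers);}
#'   \item{net}{large diffuse blobs, at least twice the NET gate.}
#' }
#' Objects are placed by rejection sampling with a retry cap; generation is
#' deterministic under a fixed seed.
#'
#' @param n_resting,n_spread,n_net Object counts per class.
#' @param stain A [stain_model()].
#' @param shape `(height, width)` in pixels.
#' @param objective `"10x"` or `"20x"`; sets the class area bands through
#'   the size gates.
#' @param seed Integer seed (optional but required for reproducibility).
#' @param marker_scale Factor in `[0, 1]` applied to the marker class means
#'   (used by [generate_timecourse()] to model signal developing over
#'   time).
#' @param margin Minimum spacing in pixels kept free around each object's
#'   bounding box.
#' @param metadata Named list (`field_id`, `time_point_min`, `stimulus`)
#'   for the returned field.
#' @return List with `field` (a [multichannel_field()]), `truth` (data
#'   frame: `id`, `class`, `centroid_row`, `centroid_col`, `area`,
#'   `mean_dna`, `mean_marker`) and `truth_labels` (integer ground-truth
#'   label map).
#' @export
generate_field <- function(n_resting, n_spread, n_net,
                           stain = stain_model("d3d9_like"),
                           shape = c(512L, 512L),
                           objective = c("20x", "10x"), seed = NULL,
                           marker_scale = 1, margin = 12L,
                           metadata = list()) {
  objective <- match.arg(objective)
  gates <- resolve_size_gates(objective)
  with_seed(seed, {
    h <- shape[1]; w <- shape[2]
    classes <- rep(c("resting", "spread", "net"),
                   c(n_resting, n_spread, n_net))
    occupied <- matrix(FALSE, h, w)
    labels <- matrix(0L, h, w)
    rows <- list()
    for (i in seq_along(classes)) {
      cls <- classes[i]
      fp <- NULL
      for (try in 1:60) {
        band <- class_area_band(cls, gates)
        target <- stats::runif(1, band[1], band[2])
        cand <- if (cls == "net") net_footprint(target)
                else lobed_footprint(target)
        if (class_area_ok(cls, sum(cand), gates)) { fp <- cand; break }
      }
      if (is.null(fp))
        stop_netquant("could not realize a footprint in its area band",
                      "netquant_density_error")
      nr <- nrow(fp); nc <- ncol(fp)
      placed <- FALSE
      for (try in 1:300) {
        r0 <- sample.int(h - nr + 1L, 1L)
        c0 <- sample.int(w - nc + 1L, 1L)
        rs <- max(1L, r0 - margin):min(h, r0 + nr - 1L + margin)
        cs <- max(1L, c0 - margin):min(w, c0 + nc - 1L + margin)
        if (!any(occupied[rs, cs])) {
          occupied[r0:(r0 + nr - 1L), c0:(c0 + nc - 1L)] <-
            occupied[r0:(r0 + nr - 1L), c0:(c0 + nc - 1L)] | fp
          sub <- labels[r0:(r0 + nr - 1L), c0:(c0 + nc - 1L)]
          sub[fp] <- i
          labels[r0:(r0 + nr - 1L), c0:(c0 + nc - 1L)] <- sub
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop_netquant(
          "could not place all objects at the requested density",
          "netquant_density_error")
      rows[[i]] <- list(id = i, class = cls)
    }
    top <- 2^stain$bit_depth - 1
    render <- function(means) {
      img <- matrix(stain$background_mean, h, w)
      for (i in seq_along(classes))
        img[labels == i] <- means[[classes[i]]]
      img <- img + stats::rnorm(h * w, 0, stain$noise_sd)
      matrix(as.integer(pmin(pmax(round(img), 0), top)), h, w)
    }
    dna <- render(as.list(stain$dna_mean))
    # unstained classes (mean <= background) stay at background; stained
    # classes scale with marker_scale but never drop below background
    mm <- lapply(stain$marker_mean, function(v)
      if (v <= stain$background_mean) stain$background_mean
      else max(stain$background_mean, v * marker_scale))
    marker <- render(mm)
    field <- multichannel_field(
      dna, marker,
      field_id = metadata$field_id %||% "synthetic",
      time_point_min = metadata$time_point_min %||% 0,
      stimulus = metadata$stimulus %||% "synthetic",
      objective = objective, bit_depth = stain$bit_depth)
    truth <- if (length(classes) == 0) {
      data.frame(id = integer(0), class = character(0),
                 centroid_row = numeric(0), centroid_col = numeric(0),
                 area = integer(0), mean_dna = numeric(0),
                 mean_marker = numeric(0), stringsAsFactors = FALSE)
    } else {
      do.call(rbind, lapply(seq_along(classes), function(i) {
        px <- which(labels == i)
        data.frame(id = i, class = classes[i],
                   centroid_row = mean((px - 1L) %% h),
                   centroid_col = mean((px - 1L) %/% h),
                   area = length(px),
                   mean_dna = mean(dna[px]),
                   mean_marker = mean(marker[px]),
                   stringsAsFactors = FALSE)
      }))
    }
    list(field = field, truth = truth, truth_labels = labels)
  })
}

# 3D9-like signal develops over the time course: absent before ~120 min,
# then ramping to full strength by 240 min. Pan-chromatin staining is
# present from the start.
marker_time_factor <- function(stain, time_point_min) {
  if (stain$name == "chromatin_like") return(1)
  if (time_point_min < 120) 0 else min(1, (time_point_min - 120) / 120)
}

#' Generate a synthetic time-course series
#'
#' One or more fields per time point with a specified class mix. Under the
#' `d3d9_like` stain model the marker signal is absent before ~120 min and
#' ramps up to full strength afterwards; under `chromatin_like` nuclei are
#' visible in the marker channel from time 0.
#'
#' @param series_spec Data frame with columns `time_point_min`,
#'   `n_resting`, `n_spread`, `n_net` and optionally `n_fields` (default
#'   1).
#' @param stain A [stain_model()].
#' @param seed Integer base seed; field `i` of the series uses `seed + i`.
#' @param shape,objective,margin Passed to [generate_field()].
#' @param stimulus Stimulus label stamped on every field.
#' @return List of [generate_field()] results, one per field.
#' @export
generate_timecourse <- function(series_spec,
                                stain = stain_model("d3d9_like"),
                                seed = NULL, shape = c(512L, 512L),
                                objective = "20x", margin = 12L,
                                stimulus = "PMA") {
  out <- list()
  counter <- 0L
  for (i in seq_len(nrow(series_spec))) {
    row <- series_spec[i, ]
    nf <- if (!is.null(row$n_fields) && !is.na(row$n_fields))
      row$n_fields else 1L
    for (f in seq_len(nf)) {
      counter <- counter + 1L
      out[[counter]] <- generate_field(
        row$n_resting, row$n_spread, row$n_net, stain = stain,
        shape = shape, objective = objective,
        seed = if (is.null(seed)) NULL else seed + counter,
        marker_scale = marker_time_factor(stain, row$time_point_min),
        margin = margin,
        metadata = list(
          field_id = sprintf("t%03d_f%02d", row$time_point_min, f),
          time_point_min = row$time_point_min, stimulus = stimulus))
    }
  }
  out
}
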