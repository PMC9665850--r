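# Independent brute-force oracles used to validate the compiled kernels,
# plus small fixture builders shared across test files.

# Bernsen oracle: explicit per-pixel scan of the clipped circular
# neighborhood, written against the method definition only.
bernsen_oracle <- function(img, radius, contrast, bit_depth = 8L) {
  nr <- nrow(img); nc <- ncol(img)
  half_scale <- 2^(bit_depth - 1L)
  out <- matrix(FALSE, nr, nc)
  for (r in seq_len(nr)) {
    rs <- max(1, r - radius):min(nr, r + radius)
    for (c in seq_len(nc)) {
      cs <- max(1, c - radius):min(nc, c + radius)
      d2 <- outer((rs - r)^2, (cs - c)^2, `+`)
      nb <- img[rs, cs, drop = FALSE][d2 <= radius^2]
      lo <- min(nb); hi <- max(nb)
      mid <- (lo + hi) / 2
      out[r, c] <- if (hi - lo >= contrast) img[r, c] > mid
                   else mid >= half_scale
    }
  }
  out
}

# Connected-component oracle: depth-first flood fill with explicit stack,
# components numbered in raster-scan (row-major) order of the first pixel.
label_oracle <- function(mask, connectivity = 8L) {
  nr <- nrow(mask); nc <- ncol(mask)
  offs <- if (connectivity == 8L)
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  else cbind(c(-1, 0, 0, 1), c(0, -1, 1, 0))
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!mask[r, c] || lab[r, c] != 0L) next
    nxt <- nxt + 1L
    stack <- list(c(r, c))
    lab[r, c] <- nxt
    while (length(stack) > 0) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (k in seq_len(nrow(offs))) {
        rr <- p[1] + offs[k, 1]; cc <- p[2] + offs[k, 2]
        if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc &&
            mask[rr, cc] && lab[rr, cc] == 0L) {
          lab[rr, cc] <- nxt
          stack[[length(stack) + 1]] <- c(rr, cc)
        }
      }
    }
  }
  lab
}

random_intensity_matrix <- function(nr, nc, top = 255L) {
  matrix(as.integer(sample(0:top, nr * nc, replace = TRUE)), nr, nc)
}

# a field whose rasters are given directly (no TIFF involved)
make_field <- function(dna, marker = NULL, ...) {
  if (is.null(marker)) marker <- matrix(0L, nrow(dna), ncol(dna))
  multichannel_field(dna, marker, ...)
}

# stain model with a binary-valued (maximal-contrast) marker channel, used
# for the manual/auto equivalence fixtures
max_contrast_stain <- function() {
  stain_model("d3d9_like", noise_sd = 0, background_mean = 0,
              marker_mean = c(resting = 0, spread = 0, net = 255),
              dna_mean = c(resting = 200, spread = 150, net = 170))
}
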