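# Independent oracles and small fixtures shared across test files.

# Brute-force MVF: triple loop over B-scans, A-scans, depth.
naive_mvf <- function(volume, seg, layer) {
  k <- match(layer, RETINAL_LAYERS)
  x <- volume$intensities
  d <- dim(x)
  out <- matrix(NA_real_, d[1], d[2])
  for (b in seq_len(d[1])) {
    for (a in seq_len(d[2])) {
      lo <- seg$boundaries[b, a, k]
      hi <- seg$boundaries[b, a, k + 1]
      if (hi > lo) {
        acc <- 0
        for (z in lo:(hi - 1)) acc <- acc + x[b, a, z + 1]
        out[b, a] <- acc / (hi - lo)
      }
    }
  }
  out
}

# Brute-force single-tile CLAHE: plain clipped histogram equalization over
# the whole image, written directly from the mapping definition.
brute_clipped_hist_eq <- function(img, clip = 0.01, bins = 256L) {
  lo <- min(img); hi <- max(img)
  if (hi == lo) return(img)
  b <- pmin(floor((img - lo) / (hi - lo) * bins), bins - 1L)
  h <- as.vector(table(factor(as.vector(b), levels = 0:(bins - 1L))))
  limit <- max(1, round(clip * length(img)))
  excess <- sum(pmax(h - limit, 0))
  h <- pmin(h, limit)
  h <- h + excess %/% bins
  r <- excess %% bins
  if (r > 0) h[seq_len(r)] <- h[seq_len(r)] + 1
  cdf <- cumsum(h) / sum(h)
  matrix(lo + (hi - lo) * cdf[b + 1L], nrow(img), ncol(img))
}

# Small synthetic configuration: zero mortality, tiny volumes, fast.
tiny_config <- function(seed = 1L, ...) {
  args <- utils::modifyList(
    list(n_per_group = 4L,
         mortality_schedule = list(WT = integer(5), TG = integer(5)),
         volume_shape = c(12L, 16L, 48L),
         rng_seed = seed),
    list(...))
  do.call(synth_config, args)
}

# A hand-buildable segmentation: constant boundary depths across the face.
flat_segmentation <- function(nb, na, depths, depth) {
  b <- array(0, c(nb, na, 6L))
  for (k in 1:6) b[, , k] <- depths[k]
  layer_segmentation(b, depth)
}
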