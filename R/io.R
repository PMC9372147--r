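# File interfaces: multi-page TIFF volumes, CSV boundaries/manifests,
# 8-bit PNG image export, YAML configs.

#' Write an OCT volume as a multi-page 16-bit TIFF
#'
#' One page per B-scan; intensities are scaled by `max_intensity` into the
#' 16-bit range.
#'
#' @param volume An [oct_volume()].
#' @param path Output file path.
#' @param max_intensity Intensity mapped to the top of the 16-bit range.
#' @return `path`, invisibly.
#' @export
write_volume_tiff <- function(volume, path, max_intensity = 1024) {
  x <- pmin(volume$intensities / max_intensity, 1)
  pages <- lapply(seq_len(dim(x)[1]), function(b) {
    # page = A-scans x depth
    matrix(x[b, , ], dim(x)[2], dim(x)[3])
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a multi-page TIFF volume written by [write_volume_tiff()]
#'
#' @param path File path.
#' @param max_intensity Scale used at write time.
#' @param meta Optional metadata list to attach.
#' @return An [oct_volume()].
#' @export
read_volume_tiff <- function(path, max_intensity = 1024, meta = list()) {
  pages <- tiff::readTIFF(path, all = TRUE)
  nb <- length(pages)
  d <- dim(pages[[1]])
  x <- array(0, c(nb, d[1], d[2]))
  for (b in seq_len(nb)) x[b, , ] <- pages[[b]]
  oct_volume(x * max_intensity, meta = meta)
}

#' Write layer boundaries as CSV
#'
#' Long format, one row per A-scan: columns `bscan`, `ascan`, `b0`..`b5`.
#'
#' @param seg A [layer_segmentation()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_boundaries_csv <- function(seg, path) {
  b <- seg$boundaries
  d <- dim(b)
  df <- expand.grid(bscan = seq_len(d[1]), ascan = seq_len(d[2]))
  for (k in 1:6) df[[paste0("b", k - 1L)]] <- as.vector(b[, , k])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read layer boundaries from CSV
#'
#' @param path File written by [write_boundaries_csv()].
#' @param depth Depth of the parent volume.
#' @return A [layer_segmentation()].
#' @export
read_boundaries_csv <- function(path, depth) {
  df <- utils::read.csv(path)
  nb <- max(df$bscan); na_ <- max(df$ascan)
  b <- array(0, c(nb, na_, 6L))
  ord <- order(df$ascan, df$bscan)
  for (k in 1:6) b[, , k] <- matrix(df[[paste0("b", k - 1L)]][ord], nb, na_)
  layer_segmentation(b, depth)
}

#' Export an image as 8-bit grayscale PNG
#'
#' Values are clamped to `[0, 255]` and quantized; intended for normalized
#' images already on the 8-bit scale (mean 128, sd 8).
#'
#' @param image 2-D matrix.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(image, path) {
  x <- pmin(pmax(image, 0), 255) / 255
  png::writePNG(x, path)
  invisible(path)
}

#' Write / read an acquisition manifest CSV
#'
#' @param manifest Data frame (e.g. from [cohort_manifest()]).
#' @param path CSV path.
#' @return `path` (write) or a data frame (read).
#' @export
write_manifest_csv <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest_csv
#' @export
read_manifest_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Read a pipeline configuration from YAML
#'
#' Nested blocks `synth`, `normalize`, `split`, `classifier`, plus a global
#' `seed`, are merged over the package defaults and converted to the
#' corresponding configuration objects.
#'
#' @param path YAML file path.
#' @return List as accepted by [run_pipeline()].
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  build_pipeline_config(raw)
}

#' Assemble a pipeline configuration from nested lists
#'
#' @param blocks Named list with optional elements `synth`, `normalize`,
#'   `split`, `classifier`, `seed`, `layers`.
#' @return List with fully-constructed configuration objects.
#' @export
build_pipeline_config <- function(blocks = list()) {
  seed <- blocks$seed %||% 1L
  synth <- do.call(synth_config,
                   utils::modifyList(list(rng_seed = seed),
                                     blocks$synth %||% list()))
  norm <- do.call(normalize_params, blocks$normalize %||% list())
  cls <- do.call(classifier_config,
                 utils::modifyList(list(seed = seed),
                                   blocks$classifier %||% list()))
  split <- utils::modifyList(list(seed = seed, test_frac = 0.2,
                                  val_frac = 0.25, train_ages = c(3, 4, 8)),
                             blocks$split %||% list())
  list(seed = seed, synth = synth, normalize = norm, classifier = cls,
       split = split, layers = blocks$layers %||% RETINAL_LAYERS)
}
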