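#' Compute a mean-value fundus image for one retinal layer
#'
#' Projects a segmented OCT volume en face: pixel `(b, a)` of the MVF image
#' is the arithmetic mean of `intensities[b, a, z]` for `z` in the 0-based
#' half-open interval `[boundary_k(b, a), boundary_{k+1}(b, a))`, i.e. the
#' mean A-scan intensity within the layer of interest — mimicking a fundus
#' photograph taken in the absence of all remaining layers.
#'
#' @param volume An [oct_volume()].
#' @param seg A [layer_segmentation()] valid for `volume`.
#' @param layer One of [RETINAL_LAYERS].
#' @param zero_thickness_policy What to do at columns where the layer has
#'   zero thickness: `"error"` (default) aborts naming the first offending
#'   `(b, a)` location; `"missing"` marks the pixel `NA`.
#' @return Object of class `mvf_image`: list with `pixels` (matrix
#'   B-scans x A-scans), `layer`, and `meta` copied from the volume.
#' @export
compute_mvf <- function(volume, seg, layer,
                        zero_thickness_policy = c("error", "missing")) {
  policy <- match.arg(zero_thickness_policy)
  k <- match(layer, RETINAL_LAYERS)
  if (is.na(k)) {
    stop_bad("unknown layer '%s' (expected one of: %s)", layer,
             paste(RETINAL_LAYERS, collapse = ", "))
  }
  x <- volume$intensities
  d <- dim(x)
  if (!all(dim(seg$boundaries)[1:2] == d[1:2]) || seg$depth != d[3]) {
    stop_bad("segmentation does not match volume dimensions")
  }
  nb <- d[1]; na_ <- d[2]; nd <- d[3]
  lo <- matrix(seg$boundaries[, , k], nb, na_)
  hi <- matrix(seg$boundaries[, , k + 1], nb, na_)
  counts <- hi - lo
  if (any(counts == 0)) {
    if (policy == "error") {
      bad <- which(counts == 0, arr.ind = TRUE)[1, ]
      stop_bad("zero-thickness %s column at (b = %d, a = %d)",
               layer, bad[1], bad[2])
    }
  }
  # cumulative depth sums with a zero slab in front: cs0[, , j + 1] equals
  # the sum of intensities at depths 0..j-1 (0-based)
  cs <- apply(x, c(1, 2), cumsum)              # (nd, nb, na)
  cs0 <- array(0, dim = c(nb, na_, nd + 1L))
  cs0[, , 2:(nd + 1L)] <- aperm(cs, c(2, 3, 1))
  bi <- as.vector(row(lo))
  ai <- as.vector(col(lo))
  top <- cs0[cbind(bi, ai, as.vector(hi) + 1L)]
  bot <- cs0[cbind(bi, ai, as.vector(lo) + 1L)]
  px <- matrix((top - bot) / as.vector(counts), nb, na_)
  px[counts == 0] <- NA_real_
  structure(list(pixels = px, layer = layer, meta = volume$meta),
            class = "mvf_image")
}

#' Compute MVF images for all five retinal layers
#'
#' Applies [compute_mvf()] once per layer, in fixed inner-to-outer order
#' (RNFL-GCL, IPL, INL, OPL, ONL).
#'
#' @inheritParams compute_mvf
#' @return Named list of five `mvf_image` objects in [RETINAL_LAYERS] order.
#' @export
compute_all_layers <- function(volume, seg,
                               zero_thickness_policy = c("error", "missing")) {
  policy <- match.arg(zero_thickness_policy)
  out <- lapply(RETINAL_LAYERS, function(l) {
    compute_mvf(volume, seg, l, zero_thickness_policy = policy)
  })
  names(out) <- RETINAL_LAYERS
  out
}

#' @export
print.mvf_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("MVF image, layer %s, %d x %d pixels", x$layer, d[1], d[2]))
  if (length(x$meta)) {
    cat(sprintf(" [%s %s %s, %s mo]", x$meta$animal_id %||% "?",
                x$meta$group %||% "?", x$meta$eye %||% "?",
                x$meta$age %||% "?"))
  }
  cat("\n")
  invisible(x)
}
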