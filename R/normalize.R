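#' Parameters of the intensity-normalization chain
#'
#' @param clahe_tiles Integer pair: CLAHE tile grid (rows, cols).
#' @param clahe_clip Clip limit as a fraction of the tile pixel count; each
#'   tile histogram bin is clipped at `max(1, round(clahe_clip * n_tile))`
#'   and the excess is redistributed uniformly.
#' @param clahe_bins Number of histogram bins.
#' @param lpf_kernel Odd side length (pixels) of the Gaussian low-pass
#'   kernel.
#' @param lpf_sigma Gaussian standard deviation in pixels.
#' @param out_scale,out_offset Final scaling of the z-scored ratio image:
#'   `out_scale * z + out_offset`, giving output mean `out_offset` and
#'   standard deviation `out_scale` (8-bit-friendly defaults 8 and 128).
#' @param eps Small positive constant guarding the element-wise division.
#' @return Object of class `normalize_params`.
#' @export
normalize_params <- function(clahe_tiles = c(8L, 8L),
                             clahe_clip = 0.01,
                             clahe_bins = 256L,
                             lpf_kernel = 121L,
                             lpf_sigma = 25,
                             out_scale = 8,
                             out_offset = 128,
                             eps = 1e-6) {
  if (lpf_kernel %% 2L != 1L) stop_bad("lpf_kernel must be odd")
  if (lpf_sigma <= 0) stop_bad("lpf_sigma must be positive")
  if (eps <= 0) stop_bad("eps must be positive")
  if (length(clahe_tiles) != 2L || any(clahe_tiles < 1L)) {
    stop_bad("clahe_tiles must be two positive integers")
  }
  structure(list(clahe_tiles = as.integer(clahe_tiles),
                 clahe_clip = clahe_clip, clahe_bins = as.integer(clahe_bins),
                 lpf_kernel = as.integer(lpf_kernel), lpf_sigma = lpf_sigma,
                 out_scale = out_scale, out_offset = out_offset, eps = eps),
            class = "normalize_params")
}

# Clip a tile histogram at `limit` counts per bin and redistribute the
# excess: floor(excess / bins) to every bin, remainder one count each to the
# lowest bins. Single pass; bins may end marginally above the limit.
clip_histogram <- function(h, limit) {
  excess <- sum(pmax(h - limit, 0))
  h <- pmin(h, limit)
  if (excess > 0) {
    nb <- length(h)
    h <- h + excess %/% nb
    rem <- excess %% nb
    if (rem > 0) h[seq_len(rem)] <- h[seq_len(rem)] + 1
  }
  h
}

#' Contrast-limited adaptive histogram equalization
#'
#' Standard CLAHE: the image range is quantized into `clahe_bins` bins, a
#' clipped-and-redistributed histogram is built per tile of a
#' `clahe_tiles` grid, each tile's cumulative distribution defines a
#' monotone intensity mapping back onto the input range
#' (`lo + (hi - lo) * cdf(bin)`), and per-pixel outputs are bilinearly
#' interpolated between the mappings of the four nearest tile centres.
#' A constant image is returned unchanged.
#'
#' @param image 2-D numeric matrix of finite values.
#' @param params A [normalize_params()].
#' @return Matrix of the same shape, values within the input range.
#' @export
clahe <- function(image, params = normalize_params()) {
  if (!is.matrix(image) || !all(is.finite(image))) {
    stop_bad("image must be a finite numeric matrix")
  }
  nr <- nrow(image); nc <- ncol(image)
  tr <- params$clahe_tiles[1]; tc <- params$clahe_tiles[2]
  if (nr < tr || nc < tc) {
    stop_bad("image (%d x %d) smaller than CLAHE tile grid (%d x %d)",
             nr, nc, tr, tc)
  }
  lo <- min(image); hi <- max(image)
  if (hi == lo) return(image)
  nb <- params$clahe_bins
  bin <- pmin(floor((image - lo) / (hi - lo) * nb), nb - 1L)  # 0-based

  row_cut <- round(seq(0L, nr, length.out = tr + 1L))
  col_cut <- round(seq(0L, nc, length.out = tc + 1L))
  luts <- array(0, dim = c(tr, tc, nb))
  cy <- numeric(tr); cx <- numeric(tc)
  for (i in seq_len(tr)) {
    ri <- (row_cut[i] + 1L):row_cut[i + 1L]
    cy[i] <- (row_cut[i] + 1L + row_cut[i + 1L]) / 2
    for (j in seq_len(tc)) {
      cj <- (col_cut[j] + 1L):col_cut[j + 1L]
      if (i == 1L) cx[j] <- (col_cut[j] + 1L + col_cut[j + 1L]) / 2
      tile_bins <- bin[ri, cj]
      h <- tabulate(as.vector(tile_bins) + 1L, nbins = nb)
      n_tile <- length(tile_bins)
      h <- clip_histogram(h, max(1, round(params$clahe_clip * n_tile)))
      luts[i, j, ] <- lo + (hi - lo) * cumsum(h) / sum(h)
    }
  }

  # bilinear interpolation between tile-centre mappings
  interp_axis <- function(pos, centres) {
    k0 <- findInterval(pos, centres)
    k0 <- pmin(pmax(k0, 1L), length(centres))
    k1 <- pmin(k0 + 1L, length(centres))
    w <- ifelse(k1 == k0, 0,
                (pos - centres[k0]) / (centres[k1] - centres[k0]))
    w[pos <= centres[1]] <- 0
    w[pos >= centres[length(centres)]] <- 0
    k1[pos >= centres[length(centres)]] <- length(centres)
    k0[pos >= centres[length(centres)]] <- length(centres)
    list(k0 = k0, k1 = k1, w = pmin(pmax(w, 0), 1))
  }
  ry <- interp_axis(seq_len(nr), cy)
  rx <- interp_axis(seq_len(nc), cx)

  bi <- as.vector(row(image)); ci <- as.vector(col(image))
  bv <- as.vector(bin) + 1L
  y0 <- ry$k0[bi]; y1 <- ry$k1[bi]; wy <- ry$w[bi]
  x0 <- rx$k0[ci]; x1 <- rx$k1[ci]; wx <- rx$w[ci]
  out <- (1 - wy) * (1 - wx) * luts[cbind(y0, x0, bv)] +
         (1 - wy) * wx       * luts[cbind(y0, x1, bv)] +
         wy       * (1 - wx) * luts[cbind(y1, x0, bv)] +
         wy       * wx       * luts[cbind(y1, x1, bv)]
  matrix(out, nr, nc)
}

# Reflect (abc|cba style, edge repeated) an out-of-range 1-based index back
# into 1..n; handles padding wider than the image via the 2n-periodic fold.
reflect_index <- function(idx, n) {
  if (n == 1L) return(rep(1L, length(idx)))
  m <- (idx - 1L) %% (2L * n)
  m[m < 0L] <- m[m < 0L] + 2L * n
  ifelse(m < n, m + 1L, 2L * n - m)
}

# Separable convolution with a normalized 1-D Gaussian along both axes,
# reflect border handling.
separable_gaussian <- function(image, sigma, half_width) {
  g <- stats::dnorm(seq(-half_width, half_width), sd = sigma)
  g <- g / sum(g)
  k <- length(g)
  conv_rows <- function(m) {
    n <- nrow(m)
    pad <- m[reflect_index(seq(1L - half_width, n + half_width), n), ,
             drop = FALSE]
    out <- matrix(0, n, ncol(m))
    for (t in seq_len(k)) {
      out <- out + g[t] * pad[t:(t + n - 1L), , drop = FALSE]
    }
    out
  }
  t(conv_rows(t(conv_rows(image))))
}

#' Gaussian low-pass filter
#'
#' Convolves the image with a normalized 2-D Gaussian kernel (default
#' 121 x 121 pixels, sigma 25), capturing broad regional intensity so that
#' dividing by it corrects uneven illumination. Borders are handled by
#' reflection.
#'
#' @inheritParams clahe
#' @return Matrix of the same shape.
#' @export
gaussian_lpf <- function(image, params = normalize_params()) {
  if (!is.matrix(image) || !all(is.finite(image))) {
    stop_bad("image must be a finite numeric matrix")
  }
  separable_gaussian(image, sigma = params$lpf_sigma,
                     half_width = (params$lpf_kernel - 1L) %/% 2L)
}

#' Z-score an image and rescale to a target mean and spread
#'
#' Subtracts the mean, divides by the standard deviation, multiplies by
#' `scale` and adds `offset`, so the result has mean `offset` and standard
#' deviation `scale`. A zero-variance image maps to a constant `offset`
#' image with a warning.
#'
#' @param image 2-D numeric matrix.
#' @param scale,offset Target standard deviation and mean.
#' @return Matrix of the same shape.
#' @export
zscore_scale <- function(image, scale = 8, offset = 128) {
  s <- stats::sd(image)
  if (!is.finite(s) || s == 0) {
    warning("degenerate (zero-variance) image; returning constant offset")
    return(matrix(offset, nrow(image), ncol(image)))
  }
  (image - mean(image)) / s * scale + offset
}

#' Full MVF intensity-normalization chain
#'
#' Applies, in order: CLAHE; Gaussian low-pass filtering of the CLAHE
#' output; element-wise division of the CLAHE image by the low-pass image
#' (plus `eps`); z-scoring of the ratio; and rescaling by
#' `out_scale` / `out_offset`. The output of a non-degenerate input has mean
#' `out_offset` (128) and standard deviation `out_scale` (8), so the chain
#' equalizes the first two intensity moments of every image and removes
#' smooth illumination gradients — discrimination downstream cannot rest on
#' simple global-intensity differences between groups.
#'
#' @inheritParams clahe
#' @return Matrix of the same shape.
#' @export
normalize_mvf <- function(image, params = normalize_params()) {
  cl <- clahe(image, params)
  lp <- gaussian_lpf(cl, params)
  ratio <- cl / (lp + params$eps)
  zscore_scale(ratio, scale = params$out_scale, offset = params$out_offset)
}

#' Training-set augmentation
#'
#' For one training image, produces exactly two new images: the vertical
#' (top-bottom) flip, and a rotation of the original by 90 or 270 degrees,
#' the angle chosen uniformly at random. The original is untouched;
#' augmentation is intended for training images only.
#'
#' @param image 2-D matrix.
#' @param seed Optional integer seed for the angle draw.
#' @return List with elements `vflip` and `rotation`; the rotation carries
#'   the chosen angle as attribute `"angle"`.
#' @export
augment <- function(image, seed = NULL) {
  with_rng(seed, {
    angle <- if (stats::runif(1) < 0.5) 90 else 270
    rot <- rotate90(image, clockwise = (angle == 90))
    attr(rot, "angle") <- angle
    list(vflip = image[nrow(image):1, , drop = FALSE], rotation = rot)
  })
}

#' Rotate a matrix image by 90 degrees
#'
#' @param image 2-D matrix.
#' @param clockwise Rotate clockwise (`TRUE`) or counter-clockwise.
#' @return Rotated matrix (dimensions transposed).
#' @export
rotate90 <- function(image, clockwise = TRUE) {
  if (clockwise) {
    t(image[nrow(image):1, , drop = FALSE])
  } else {
    t(image)[ncol(image):1, , drop = FALSE]
  }
}
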