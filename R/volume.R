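# Synthetic segmented OCT volumes: smooth layered depth profile, per-layer
# texture fields, additive noise, and the planted transgenic effect.

# Smooth zero-mean random field: white noise blurred with a Gaussian of the
# given sigma (reflect borders), rescaled to unit sd, then scaled by amp.
smooth_field <- function(nrow, ncol, sigma, amp) {
  if (amp == 0) return(matrix(0, nrow, ncol))
  f <- matrix(stats::rnorm(nrow * ncol), nrow, ncol)
  f <- separable_gaussian(f, sigma = sigma,
                          half_width = max(1L, ceiling(3 * sigma)))
  f <- f - mean(f)
  s <- stats::sd(f)
  if (s == 0) return(matrix(0, nrow, ncol))
  f / s * amp
}

#' Construct an OCT volume object
#'
#' @param intensities 3-D array (B-scans x A-scans x depth), non-negative
#'   finite values.
#' @param meta Named list of acquisition metadata (`animal_id`, `group`,
#'   `eye`, `age`).
#' @return Object of class `oct_volume`.
#' @export
oct_volume <- function(intensities, meta = list()) {
  if (length(dim(intensities)) != 3L) stop_bad("intensities must be a 3-D array")
  if (!all(is.finite(intensities))) stop_bad("intensities must be finite")
  if (any(intensities < 0)) stop_bad("intensities must be non-negative")
  structure(list(intensities = intensities, meta = meta), class = "oct_volume")
}

#' Construct a layer segmentation object
#'
#' Six boundary surfaces delimit the five retinal layers: layer `k` occupies
#' the half-open depth interval `[boundary_k, boundary_{k+1})` in 0-based
#' depth indices.
#'
#' @param boundaries 3-D array (B-scans x A-scans x 6) of 0-based depth
#'   indices, monotone non-decreasing along the third dimension and within
#'   `[0, depth]`.
#' @param depth Depth (number of samples per A-scan) of the parent volume.
#' @return Object of class `layer_segmentation`.
#' @export
layer_segmentation <- function(boundaries, depth) {
  d <- dim(boundaries)
  if (length(d) != 3L || d[3] != 6L) {
    stop_bad("boundaries must be (n_bscans x n_ascans x 6)")
  }
  if (any(boundaries < 0) || any(boundaries > depth)) {
    stop_bad("boundaries must lie within [0, depth]")
  }
  for (k in 1:5) {
    if (any(boundaries[, , k + 1] < boundaries[, , k])) {
      stop_bad("boundaries must be monotone non-decreasing across surfaces")
    }
  }
  structure(list(boundaries = boundaries, depth = depth),
            class = "layer_segmentation")
}

# Layer thickness fractions of the usable depth, inner to outer.
layer_thickness_fractions <- c(0.18, 0.22, 0.15, 0.12, 0.33)

#' Generate one synthetic segmented OCT volume
#'
#' Builds a smooth layered depth profile: each of the five retinal layers is
#' filled with its baseline intensity plus a smooth 2-D texture field, then
#' additive Gaussian noise of sd `config$noise_sd` is applied (values clamped
#' at zero). For transgenic animals, each layer in `config$affected_layers`
#' additionally receives a smooth low-spatial-frequency texture of amplitude
#' `effect_size * maturity_factor(age)`. All random draws are made regardless
#' of group, so at `effect_size = 0` a WT and a TG acquisition generated from
#' the same seed are identical.
#'
#' @param animal An `animal_record` from [generate_cohort()].
#' @param age Imaging age in months; must be in `animal$ages_alive`.
#' @param eye `"OD"` or `"OS"`.
#' @param config A [synth_config()].
#' @param seed Optional integer seed; by default derived deterministically
#'   from `config$rng_seed` and the acquisition identity.
#' @return List with elements `volume` ([oct_volume()]) and `seg`
#'   ([layer_segmentation()]).
#' @export
generate_volume <- function(animal, age, eye, config, seed = NULL) {
  if (!age %in% animal$ages_alive) {
    stop_bad("animal %s is not alive at age %s months", animal$animal_id, age)
  }
  if (!eye %in% c("OD", "OS")) stop_bad("eye must be OD or OS")
  if (is.null(seed)) {
    seed <- hash_seed(config$rng_seed,
                      sprintf("%s|%s|%s", animal$animal_id, eye, age))
  }
  nb <- config$volume_shape[1]
  na_ <- config$volume_shape[2]
  nd <- config$volume_shape[3]
  ramp <- maturity_factor(age, config)

  with_rng(seed, {
    # --- geometry: inner boundary plus cumulative per-layer thicknesses
    top_base <- round(0.15 * nd)
    top <- round(top_base + smooth_field(nb, na_, config$effect_sigma,
                                         config$boundary_jitter))
    usable <- floor(0.55 * nd)
    thick_base <- pmax(1, round(layer_thickness_fractions * usable))
    bnd <- array(0, dim = c(nb, na_, 6L))
    bnd[, , 1] <- pmax(top, 0)
    # integer per-layer thickness increments, each at least one voxel, so
    # every layer keeps positive thickness by construction
    for (k in 1:5) {
      th <- round(thick_base[k] + smooth_field(nb, na_, config$effect_sigma,
                                               config$boundary_jitter))
      bnd[, , k + 1] <- bnd[, , k] + pmax(1, th)
    }
    # overflowing columns are first slid up, then (if still too deep)
    # compressed from the bottom while keeping >= 1 voxel per layer
    shift <- pmin(pmax(bnd[, , 6] - nd, 0), bnd[, , 1])
    if (any(shift > 0)) {
      for (k in 1:6) bnd[, , k] <- bnd[, , k] - shift
    }
    if (any(bnd[, , 6] > nd)) {
      bnd[, , 6] <- pmin(bnd[, , 6], nd)
      for (k in 5:1) bnd[, , k] <- pmin(bnd[, , k], bnd[, , k + 1] - 1L)
      if (any(bnd[, , 1] < 0)) {
        stop_bad("volume depth %d too small for the layer stack", nd)
      }
    }

    # --- intensities
    vol <- array(config$background_intensity, dim = c(nb, na_, nd))
    zmat <- matrix(rep(0:(nd - 1L), each = nb * na_), nrow = nb * na_)
    is_tg <- identical(animal$group, "TG")
    for (k in 1:5) {
      layer <- RETINAL_LAYERS[k]
      tex <- smooth_field(nb, na_, config$effect_sigma, config$texture_amp)
      # effect field drawn for every layer/acquisition so that the RNG
      # stream does not depend on group or effect size
      eff <- smooth_field(nb, na_, config$effect_sigma, 1)
      amp <- if (is_tg && layer %in% config$affected_layers) {
        config$effect_size * ramp
      } else 0
      base <- config$baseline_intensity[[layer]] + tex + amp * eff
      lo <- as.vector(bnd[, , k])
      hi <- as.vector(bnd[, , k + 1])
      inside <- (zmat >= lo) & (zmat < hi)   # recycled per column
      vol_mat <- matrix(vol, nrow = nb * na_)
      vol_mat[inside] <- rep(as.vector(base), times = nd)[inside]
      vol <- array(vol_mat, dim = c(nb, na_, nd))
    }
    if (config$noise_sd > 0) {
      vol <- vol + array(stats::rnorm(length(vol), 0, config$noise_sd),
                         dim = dim(vol))
    }
    vol <- pmax(vol, 0)
    list(volume = oct_volume(vol, meta = list(animal_id = animal$animal_id,
                                              group = animal$group,
                                              eye = eye, age = age)),
         seg = layer_segmentation(bnd, nd))
  })
}
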