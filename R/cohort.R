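#' Default mortality schedule
#'
#' Deaths per inter-age interval for each group, for the default six-age
#' design (1, 2, 3, 4, 8, 12 months). Entry `k` of each vector counts
#' animals dying between age `k` and age `k + 1`. The default reproduces a
#' cohort in which 7 of 57 wild-type and 13 of 57 transgenic animals die
#' over the study window: WT deaths 4, 0, 0, 2, 1 and TG deaths 1, 1, 2, 4,
#' 5 across the intervals 1-2, 2-3, 3-4, 4-8 and 8-12 months.
#'
#' @param n_ages Number of imaging ages (the schedule has `n_ages - 1`
#'   intervals).
#' @return Named list with integer vectors `WT` and `TG`.
#' @export
default_mortality <- function(n_ages = 6L) {
  if (n_ages == 6L) {
    list(WT = c(4L, 0L, 0L, 2L, 1L), TG = c(1L, 1L, 2L, 4L, 5L))
  } else {
    list(WT = integer(n_ages - 1L), TG = integer(n_ages - 1L))
  }
}

#' Default per-age body-weight parameters
#'
#' Mean and standard deviation of body weight (grams) at each imaging age,
#' used as cohort metadata only (weights never influence image generation).
#'
#' @return Data frame with columns `age`, `mean`, `sd`.
#' @export
default_weights <- function() {
  data.frame(
    age  = c(1, 2, 3, 4, 8, 12),
    mean = c(14.9, 22.4, 25.4, 27.2, 31.6, 33.5),
    sd   = c(2.6, 2.0, 2.1, 2.1, 3.4, 3.8)
  )
}

#' Configuration for the synthetic OCT cohort generator
#'
#' Bundles every knob of the synthetic cohort: design (animals per group,
#' imaging ages, mortality, weights), volume geometry, intensity model, and
#' the planted group effect. The planted effect is an additive
#' low-spatial-frequency texture of amplitude
#' `effect_size * maturity_factor(age)` added to the `affected_layers` of
#' transgenic animals only; it is a controllable stand-in for a real
#' biological contrast, not a model of one.
#'
#' @param n_per_group Animals per group (default 57).
#' @param ages_months Strictly increasing imaging ages in months.
#' @param effect_size Non-negative amplitude (intensity units) of the
#'   planted transgenic texture effect at full maturity.
#' @param affected_layers Subset of [RETINAL_LAYERS] carrying the planted
#'   effect. Defaults to the three innermost layers.
#' @param maturity_onset_weeks,maturity_full_weeks Maturity ramp anchors in
#'   postnatal weeks: the effect is 0 at or below onset, full at or above
#'   `maturity_full_weeks`, linear in between (1 month = 4.345 weeks).
#' @param mortality_schedule List with per-group integer vectors of deaths
#'   per inter-age interval; see [default_mortality()].
#' @param weight_params Data frame `age`, `mean`, `sd` of body weight in
#'   grams; see [default_weights()].
#' @param volume_shape Integer triple: B-scans, A-scans, depth samples.
#' @param noise_sd Standard deviation of additive voxel noise.
#' @param baseline_intensity Named per-layer mean intensity.
#' @param background_intensity Intensity outside the neuroretina.
#' @param texture_amp Amplitude of the per-layer smooth texture field shared
#'   by both groups (intensity units; 0 disables).
#' @param boundary_jitter Amplitude (voxels) of smooth spatial variation of
#'   layer boundaries; 0 gives perfectly flat layers.
#' @param effect_sigma Spatial smoothness (pixels) of the planted effect
#'   field (and of the shared texture fields).
#' @param cell_counts Optional data frame `group`, `eye`, `age`, `n` capping
#'   the number of acquisitions retained per design cell, emulating
#'   quality-based exclusions so a printed acquisition table can be matched
#'   exactly.
#' @param rng_seed Integer seed controlling every random draw derived from
#'   this configuration.
#' @return Object of class `synth_config` (a validated list).
#' @export
synth_config <- function(n_per_group = 57L,
                         ages_months = c(1, 2, 3, 4, 8, 12),
                         effect_size = 10,
                         affected_layers = c("RNFL-GCL", "IPL", "INL"),
                         maturity_onset_weeks = 4,
                         maturity_full_weeks = 15,
                         mortality_schedule = default_mortality(length(ages_months)),
                         weight_params = default_weights(),
                         volume_shape = c(32L, 64L, 128L),
                         noise_sd = 10,
                         baseline_intensity = c("RNFL-GCL" = 170, "IPL" = 130,
                                                "INL" = 90, "OPL" = 120,
                                                "ONL" = 80),
                         background_intensity = 40,
                         texture_amp = 8,
                         boundary_jitter = 1.5,
                         effect_sigma = 6,
                         cell_counts = NULL,
                         rng_seed = 1L) {
  cfg <- list(
    n_per_group = as.integer(n_per_group),
    ages_months = as.numeric(ages_months),
    effect_size = effect_size,
    affected_layers = affected_layers,
    maturity_onset_weeks = maturity_onset_weeks,
    maturity_full_weeks = maturity_full_weeks,
    mortality_schedule = lapply(mortality_schedule, as.integer),
    weight_params = weight_params,
    volume_shape = as.integer(volume_shape),
    noise_sd = noise_sd,
    baseline_intensity = baseline_intensity,
    background_intensity = background_intensity,
    texture_amp = texture_amp,
    boundary_jitter = boundary_jitter,
    effect_sigma = effect_sigma,
    cell_counts = cell_counts,
    rng_seed = as.integer(rng_seed)
  )
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  if (cfg$n_per_group < 1L) stop_bad("n_per_group must be >= 1")
  if (any(diff(cfg$ages_months) <= 0)) {
    stop_bad("ages_months must be strictly increasing")
  }
  if (!is.numeric(cfg$effect_size) || cfg$effect_size < 0) {
    stop_bad("effect_size must be a non-negative number")
  }
  if (!all(cfg$affected_layers %in% RETINAL_LAYERS)) {
    stop_bad("affected_layers must be a subset of RETINAL_LAYERS")
  }
  if (cfg$maturity_full_weeks < cfg$maturity_onset_weeks) {
    stop_bad("maturity_full_weeks must be >= maturity_onset_weeks")
  }
  if (length(cfg$volume_shape) != 3L || any(cfg$volume_shape < 2L)) {
    stop_bad("volume_shape must be three integers, all >= 2")
  }
  n_int <- length(cfg$ages_months) - 1L
  for (g in STUDY_GROUPS) {
    sched <- cfg$mortality_schedule[[g]]
    if (is.null(sched) || length(sched) != n_int) {
      stop_bad("mortality_schedule$%s must have %d intervals", g, n_int)
    }
    if (any(sched < 0L)) stop_bad("mortality counts must be non-negative")
    if (sum(sched) > cfg$n_per_group) {
      stop_bad("mortality_schedule$%s exceeds cohort size (%d > %d)",
               g, sum(sched), cfg$n_per_group)
    }
  }
  if (!all(cfg$ages_months %in% cfg$weight_params$age)) {
    stop_bad("weight_params must cover every imaging age")
  }
  if (!all(RETINAL_LAYERS %in% names(cfg$baseline_intensity))) {
    stop_bad("baseline_intensity must name all five layers")
  }
  invisible(cfg)
}

#' Maturity factor of the planted group effect
#'
#' Linear ramp in postnatal weeks describing central-nervous-system
#' maturation: 0 at or below `maturity_onset_weeks`, 1 at or above
#' `maturity_full_weeks`, linear in between. Ages are converted as
#' 1 month = 4.345 weeks.
#'
#' @param age_months Non-negative age(s) in months.
#' @param config A [synth_config()].
#' @return Numeric in `[0, 1]`, same length as `age_months`.
#' @export
maturity_factor <- function(age_months, config) {
  if (any(age_months < 0)) stop_bad("age_months must be non-negative")
  wk <- age_months * 4.345
  onset <- config$maturity_onset_weeks
  full <- config$maturity_full_weeks
  out <- ifelse(wk >= full, 1,
                ifelse(wk <= onset, 0, (wk - onset) / (full - onset)))
  pmin(1, pmax(0, out))
}

#' Generate a synthetic animal cohort
#'
#' Creates `n_per_group` animals per group, applies the mortality schedule
#' (each death truncates an animal's `ages_alive` to a prefix of the age
#' list), and draws per-age body weights from the configured normal
#' distributions. Which animals die is random but fully determined by
#' `config$rng_seed`.
#'
#' @param config A [synth_config()].
#' @return List of `animal_record` objects, each with fields `animal_id`,
#'   `group`, `eyes`, `ages_alive`, `weight_by_age`.
#' @export
generate_cohort <- function(config) {
  validate_synth_config(config)
  ages <- config$ages_months
  wp <- config$weight_params
  with_rng(config$rng_seed, {
    cohort <- list()
    for (g in STUDY_GROUPS) {
      n <- config$n_per_group
      sched <- config$mortality_schedule[[g]]
      # shuffle, then hand deaths out interval by interval
      order_ids <- sample.int(n)
      death_interval <- rep(NA_integer_, n)
      k <- 1L
      for (iv in seq_along(sched)) {
        if (sched[iv] > 0L) {
          death_interval[order_ids[k:(k + sched[iv] - 1L)]] <- iv
          k <- k + sched[iv]
        }
      }
      for (i in seq_len(n)) {
        alive <- if (is.na(death_interval[i])) ages else ages[seq_len(death_interval[i])]
        w <- vapply(alive, function(a) {
          row <- wp[wp$age == a, ]
          stats::rnorm(1, row$mean, row$sd)
        }, numeric(1))
        names(w) <- as.character(alive)
        cohort[[length(cohort) + 1L]] <- structure(
          list(animal_id = sprintf("%s%03d", g, i),
               group = g,
               eyes = c("OD", "OS"),
               ages_alive = alive,
               weight_by_age = w),
          class = "animal_record")
      }
    }
    cohort
  })
}

#' Acquisition manifest for a cohort
#'
#' Expands a cohort into one row per acquisition (animal x eye x alive age).
#' When `config$cell_counts` is set, each (group, eye, age) cell is randomly
#' subsampled to the requested count, emulating quality-based exclusions so
#' printed per-cell acquisition tables can be matched exactly.
#'
#' @param cohort Output of [generate_cohort()].
#' @param config The [synth_config()] used to build the cohort.
#' @return Data frame with columns `animal_id`, `group`, `eye`, `age`,
#'   `weight`.
#' @export
cohort_manifest <- function(cohort, config) {
  rows <- do.call(rbind, lapply(cohort, function(an) {
    expand.grid(animal_id = an$animal_id, group = an$group,
                eye = an$eyes, age = an$ages_alive,
                stringsAsFactors = FALSE)
  }))
  rows$weight <- mapply(function(id, age) {
    an <- Filter(function(a) a$animal_id == id, cohort)[[1]]
    unname(an$weight_by_age[as.character(age)])
  }, rows$animal_id, rows$age)
  rows <- rows[order(rows$group, rows$animal_id, rows$eye, rows$age), ]
  rownames(rows) <- NULL
  cc <- config$cell_counts
  if (!is.null(cc)) {
    keep <- with_rng(hash_seed(config$rng_seed, "cell_counts"), {
      unlist(lapply(seq_len(nrow(cc)), function(i) {
        idx <- which(rows$group == cc$group[i] & rows$eye == cc$eye[i] &
                       rows$age == cc$age[i])
        if (length(idx) < cc$n[i]) {
          stop_bad("cell_counts asks for %d acquisitions in %s/%s/age %s but only %d exist",
                   cc$n[i], cc$group[i], cc$eye[i], cc$age[i], length(idx))
        }
        sort(sample(idx, cc$n[i]))
      }))
    })
    rows <- rows[sort(keep), ]
    rownames(rows) <- NULL
  }
  rows
}

#' @export
print.synth_config <- function(x, ...) {
  cat("Synthetic OCT cohort configuration\n")
  cat(sprintf("  %d animals/group, ages (months): %s\n", x$n_per_group,
              paste(x$ages_months, collapse = ", ")))
  cat(sprintf("  volume %d x %d x %d (B-scans x A-scans x depth), noise sd %.3g\n",
              x$volume_shape[1], x$volume_shape[2], x$volume_shape[3],
              x$noise_sd))
  cat(sprintf("  planted effect %.3g in [%s], maturity ramp %.3g-%.3g weeks\n",
              x$effect_size, paste(x$affected_layers, collapse = ", "),
              x$maturity_onset_weeks, x$maturity_full_weeks))
  invisible(x)
}
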