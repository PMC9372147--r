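#' Generate normalized MVF images for a whole manifest
#'
#' For each acquisition in the manifest, generates the synthetic volume,
#' projects the requested layers to MVF images, and (optionally) runs the
#' normalization chain. Volumes are created and discarded one at a time so
#' memory stays proportional to the image set, not the voxel data.
#'
#' @param manifest Acquisition data frame from [cohort_manifest()].
#' @param cohort The cohort the manifest came from.
#' @param config The [synth_config()] used for generation.
#' @param layers Which layers to project (default all five).
#' @param norm A [normalize_params()], or `NULL` to skip normalization.
#' @return List with `manifest` and `images`: a named list (per layer) of
#'   lists of matrices, parallel to the manifest rows.
#' @export
build_mvf_dataset <- function(manifest, cohort, config,
                              layers = RETINAL_LAYERS,
                              norm = normalize_params()) {
  by_id <- stats::setNames(cohort, vapply(cohort, `[[`, "", "animal_id"))
  images <- stats::setNames(
    replicate(length(layers), vector("list", nrow(manifest)),
              simplify = FALSE), layers)
  for (i in seq_len(nrow(manifest))) {
    an <- by_id[[manifest$animal_id[i]]]
    gen <- generate_volume(an, manifest$age[i], manifest$eye[i], config)
    for (l in layers) {
      img <- compute_mvf(gen$volume, gen$seg, l)$pixels
      if (!is.null(norm)) img <- normalize_mvf(img, norm)
      images[[l]][[i]] <- img
    }
  }
  list(manifest = manifest, images = images)
}

#' Assemble per-layer image sets for training and evaluation
#'
#' Pulls the train/val/test images of one layer out of a
#' [build_mvf_dataset()] result according to a [select_scenario()]
#' selection, and augments the training bucket only (tripling it: original
#' + vertical flip + random 90/270 rotation). A 90/270 rotation of a
#' non-square image changes its shape, which the fixed-input classifier
#' cannot accept, so for non-square inputs the rotated copy is replaced by
#' the shape-preserving 180-degree rotation.
#'
#' @param dataset A [build_mvf_dataset()] result.
#' @param sets A [select_scenario()] result.
#' @param layer One of [RETINAL_LAYERS] present in the dataset.
#' @param seed Integer seed for the augmentation angle draws.
#' @param augment_train Augment the training bucket (default `TRUE`).
#' @return List of `train`, `val`, `test`, each with `images` and `labels`.
#' @export
scenario_image_sets <- function(dataset, sets, layer, seed = 1L,
                                augment_train = TRUE) {
  keyd <- paste(dataset$manifest$animal_id, dataset$manifest$eye,
                dataset$manifest$age, sep = "|")
  grab <- function(df) {
    idx <- match(paste(df$animal_id, df$eye, df$age, sep = "|"), keyd)
    list(images = dataset$images[[layer]][idx], labels = df$group)
  }
  tr <- grab(sets$train)
  va <- grab(sets$val)
  te <- grab(sets$test)
  if (augment_train && length(tr$images)) {
    aug_imgs <- list()
    aug_labs <- character(0)
    with_rng(hash_seed(seed, paste0("augment|", layer)), {
      for (i in seq_along(tr$images)) {
        a <- augment(tr$images[[i]])
        square <- nrow(tr$images[[i]]) == ncol(tr$images[[i]])
        rot <- if (square) a$rotation else {
          # shape-preserving stand-in for the rotated copy on non-square
          # images: 180-degree rotation (two flips)
          tr$images[[i]][nrow(tr$images[[i]]):1, ncol(tr$images[[i]]):1]
        }
        aug_imgs <- c(aug_imgs, list(a$vflip, rot))
        aug_labs <- c(aug_labs, rep(tr$labels[i], 2L))
      }
    })
    tr$images <- c(tr$images, aug_imgs)
    tr$labels <- c(tr$labels, aug_labs)
  }
  list(train = tr, val = va, test = te)
}

#' Run the full synthetic-cohort classification pipeline
#'
#' Chains every stage end to end: cohort synthesis, per-acquisition MVF
#' projection, intensity normalization, animal-level splitting, per-layer
#' classifier training, and evaluation under both test scenarios. Writes
#' manifests, split assignments, per-layer models, a metrics table
#' (layer x scenario), the per-age error table over the test animals'
#' acquisitions at all ages, and a log of stage parameters and seeds into
#' `out_dir`.
#'
#' @param config List from [build_pipeline_config()] or
#'   [read_pipeline_config()].
#' @param out_dir Output run directory (created if missing).
#' @return Invisibly, a list with `out_dir`, `metrics` (data frame),
#'   `error_table`, and `models`.
#' @export
run_pipeline <- function(config, out_dir = tempfile("octfundus_run_")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(out_dir, "log.txt")
  say <- function(...) cat(sprintf(...), "\n", file = logf, append = TRUE)
  say("octfundus pipeline run, seed %d", config$seed)

  cohort <- generate_cohort(config$synth)
  manifest <- cohort_manifest(cohort, config$synth)
  write_manifest_csv(manifest, file.path(out_dir, "manifest.csv"))
  say("cohort: %d animals, %d acquisitions", length(cohort), nrow(manifest))

  dataset <- build_mvf_dataset(manifest, cohort, config$synth,
                               layers = config$layers,
                               norm = config$normalize)
  say("built %d normalized MVF images per layer", nrow(manifest))

  assignment <- assign_split(cohort, seed = config$split$seed,
                             test_frac = config$split$test_frac,
                             val_frac = config$split$val_frac,
                             train_ages = config$split$train_ages)
  write_manifest_csv(as.data.frame(assignment),
                     file.path(out_dir, "split_assignment.csv"))

  metrics_rows <- list()
  models <- list()
  all_preds <- list()
  for (layer in config$layers) {
    scen_sets <- select_scenario(assignment, manifest, "within_age")
    audit_split(assignment, scen_sets)
    sets <- scenario_image_sets(dataset, scen_sets, layer,
                                seed = config$seed)
    cls_cfg <- config$classifier
    cls_cfg$seed <- hash_seed(config$seed, paste0("train|", layer))
    model <- train_layer_model(sets$train, sets$val, cls_cfg, layer = layer)
    models[[layer]] <- model
    saveRDS(model, file.path(out_dir, sprintf("model_%s.rds",
                                              gsub("[^A-Za-z0-9]", "_", layer))))
    say("trained %s: best epoch %d, val loss %.4f", layer,
        model$best_epoch, model$val_loss)

    for (scenario in c("within_age", "outside_age")) {
      sc <- select_scenario(assignment, manifest, scenario)
      te <- scenario_image_sets(dataset, sc, layer, augment_train = FALSE)$test
      pred <- predict_mvf(model, te$images)
      cm <- confusion_from_predictions(te$labels, pred$label)
      mr <- compute_metrics(cm)
      metrics_rows[[length(metrics_rows) + 1L]] <-
        cbind(data.frame(layer = layer, scenario = scenario), mr)
      all_preds[[length(all_preds) + 1L]] <-
        data.frame(layer = layer, scenario = scenario,
                   animal_id = sc$test$animal_id, eye = sc$test$eye,
                   age = sc$test$age, group = sc$test$group,
                   truth = te$labels, predicted = pred$label,
                   probability = pred$probability)
    }
  }

  metrics <- do.call(rbind, metrics_rows)
  utils::write.csv(metrics, file.path(out_dir, "metrics.csv"),
                   row.names = FALSE)
  preds <- do.call(rbind, all_preds)
  utils::write.csv(preds, file.path(out_dir, "predictions.csv"),
                   row.names = FALSE)

  et <- build_error_table(preds)
  utils::write.csv(et$cells, file.path(out_dir, "error_table.csv"),
                   row.names = FALSE)
  gt <- grand_total(et)
  say("grand total errors: %d/%d (%.1f%%)", gt$errors, gt$cases, gt$pct)
  jsonlite::write_json(
    list(seed = config$seed,
         metrics = metrics,
         layer_totals = layer_totals(et),
         grand_total = gt),
    file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA)

  invisible(list(out_dir = out_dir, metrics = metrics, error_table = et,
                 models = models, predictions = preds))
}
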