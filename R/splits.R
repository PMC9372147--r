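#' Animal-level train / validation / test assignment
#'
#' Splits each group's animals into test (20%), then the remainder into
#' train (75%) and validation (25%), with round-half-up counts at the animal
#' level (57 animals per group gives 11 test, then 34 train and 12
#' validation). The unit of assignment is the animal: both eyes and every
#' age of one animal share a single bucket, so no animal's data can leak
#' across sets. Assignment is stratified by group and deterministic under a
#' fixed seed.
#'
#' @param cohort List of animal records ([generate_cohort()]) or a data
#'   frame with columns `animal_id` and `group`.
#' @param seed Integer seed.
#' @param test_frac,val_frac Test fraction of each group, and validation
#'   fraction of the non-test remainder.
#' @param train_ages Ages (months) admissible for training and validation
#'   acquisitions.
#' @return Object of class `split_assignment`: data frame `animal_id`,
#'   `group`, `bucket` with attribute `train_ages`.
#' @export
assign_split <- function(cohort, seed = 1L, test_frac = 0.2, val_frac = 0.25,
                         train_ages = c(3, 4, 8)) {
  animals <- if (is.data.frame(cohort)) {
    unique(cohort[, c("animal_id", "group")])
  } else {
    data.frame(animal_id = vapply(cohort, `[[`, "", "animal_id"),
               group = vapply(cohort, `[[`, "", "group"),
               stringsAsFactors = FALSE)
  }
  out <- with_rng(seed, {
    do.call(rbind, lapply(split(animals, animals$group), function(gr) {
      n <- nrow(gr)
      n_test <- round_half_up(test_frac * n)
      n_val <- round_half_up(val_frac * (n - n_test))
      n_train <- n - n_test - n_val
      if (n_test < 1 || n_val < 1 || n_train < 1) {
        stop_bad("group %s too small (%d animals) to populate train/val/test",
                 gr$group[1], n)
      }
      perm <- sample.int(n)
      bucket <- character(n)
      bucket[perm[seq_len(n_test)]] <- "test"
      bucket[perm[n_test + seq_len(n_val)]] <- "val"
      bucket[perm[(n_test + n_val) + seq_len(n_train)]] <- "train"
      data.frame(animal_id = gr$animal_id, group = gr$group, bucket = bucket,
                 stringsAsFactors = FALSE)
    }))
  })
  rownames(out) <- NULL
  structure(out, class = c("split_assignment", "data.frame"),
            train_ages = train_ages)
}

#' Materialize acquisition lists for a test scenario
#'
#' Train and validation sets always contain only acquisitions at the
#' training ages. The test set depends on the scenario: `"within_age"`
#' takes test animals' acquisitions at the training ages; `"outside_age"`
#' takes exclusively the ages outside the training window (younger and
#' older animals), probing stage-independent generalization.
#'
#' @param assignment A [assign_split()] result.
#' @param manifest Acquisition data frame (`animal_id`, `group`, `eye`,
#'   `age`, ...), e.g. from [cohort_manifest()].
#' @param scenario `"within_age"` or `"outside_age"`.
#' @return List of data frames `train`, `val`, `test`.
#' @export
select_scenario <- function(assignment, manifest,
                            scenario = c("within_age", "outside_age")) {
  if (!scenario[1] %in% c("within_age", "outside_age")) {
    stop_bad("unknown scenario '%s'", scenario[1])
  }
  scenario <- match.arg(scenario)
  train_ages <- attr(assignment, "train_ages")
  m <- merge(manifest, as.data.frame(assignment)[, c("animal_id", "bucket")],
             by = "animal_id")
  test_ages <- if (scenario == "within_age") {
    train_ages
  } else {
    setdiff(sort(unique(manifest$age)), train_ages)
  }
  pick <- function(b, ages) {
    out <- m[m$bucket == b & m$age %in% ages, , drop = FALSE]
    out <- out[order(out$animal_id, out$eye, out$age), ]
    rownames(out) <- NULL
    out
  }
  list(train = pick("train", train_ages),
       val = pick("val", train_ages),
       test = pick("test", test_ages))
}

#' Audit a split for animal-level leakage and age restrictions
#'
#' Checks that every animal sits in exactly one bucket, that no acquisition
#' appears in more than one materialized set, and that train and validation
#' contain only training-age acquisitions. Errors on the first violation.
#'
#' @param assignment A [assign_split()] result.
#' @param sets Output of [select_scenario()].
#' @return `TRUE`, invisibly.
#' @export
audit_split <- function(assignment, sets) {
  if (anyDuplicated(assignment$animal_id)) {
    stop_bad("animal assigned to more than one bucket")
  }
  train_ages <- attr(assignment, "train_ages")
  for (b in c("train", "val")) {
    if (!all(sets[[b]]$age %in% train_ages)) {
      stop_bad("%s set contains acquisitions outside the training ages", b)
    }
  }
  ids <- lapply(sets, function(s) unique(s$animal_id))
  if (length(intersect(ids$train, ids$val)) ||
      length(intersect(ids$train, ids$test)) ||
      length(intersect(ids$val, ids$test))) {
    stop_bad("animal appears in more than one of train/val/test")
  }
  keys <- unlist(lapply(sets, function(s) {
    paste(s$animal_id, s$eye, s$age, sep = "|")
  }))
  if (anyDuplicated(keys)) stop_bad("acquisition appears in more than one set")
  invisible(TRUE)
}
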