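# Shared synthetic-recovery experiment: generate a 20-animal-per-group
# cohort, train the INL-layer classifier on within-age data, and evaluate
# both test scenarios. Used by the parameter-recovery and stage-dependence
# acceptance tests; defined here so the runs happen once per test session.

recovery_run <- function(seed, effect_size, onset_weeks = 0,
                         full_weeks = 0) {
  cfg <- synth_config(
    n_per_group = 20L, effect_size = effect_size, affected_layers = "INL",
    maturity_onset_weeks = onset_weeks, maturity_full_weeks = full_weeks,
    mortality_schedule = list(WT = integer(5), TG = integer(5)),
    rng_seed = seed)
  co <- generate_cohort(cfg)
  man <- cohort_manifest(co, cfg)
  ds <- build_mvf_dataset(man, co, cfg, layers = "INL")
  asn <- assign_split(co, seed = seed)
  within <- select_scenario(asn, man, "within_age")
  outside <- select_scenario(asn, man, "outside_age")
  im_w <- scenario_image_sets(ds, within, "INL", seed = seed)
  model <- train_layer_model(im_w$train, im_w$val,
                             classifier_config(seed = seed), layer = "INL")
  pr_w <- predict_mvf(model, im_w$test$images)
  im_o <- scenario_image_sets(ds, outside, "INL", seed = seed,
                              augment_train = FALSE)
  pr_o <- predict_mvf(model, im_o$test$images)
  list(within = mean(pr_w$label == im_w$test$labels),
       outside = mean(pr_o$label == im_o$test$labels),
       outside_err_by_age = tapply(pr_o$label != im_o$test$labels,
                                   outside$test$age, mean))
}
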