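test_that("default cohort has 57 animals per group with 7 and 13 deaths", {
  cfg <- synth_config(rng_seed = 11)
  co <- generate_cohort(cfg)
  groups <- vapply(co, `[[`, "", "group")
  expect_equal(sum(groups == "WT"), 57L)
  expect_equal(sum(groups == "TG"), 57L)
  n_ages <- vapply(co, function(a) length(a$ages_alive), 0L)
  expect_equal(sum(n_ages[groups == "WT"] < 6L), 7L)
  expect_equal(sum(n_ages[groups == "TG"] < 6L), 13L)
  # deaths land in the configured intervals: alive-prefix lengths by group
  tg_prefix <- sort(n_ages[groups == "TG" & n_ages < 6L])
  expect_equal(tg_prefix, c(1L, 2L, 3L, 3L, 4L, 4L, 4L, 4L, 5L, 5L, 5L, 5L, 5L))
})

test_that("ages_alive is always a prefix of the age list and weights cover it", {
  cfg <- synth_config(n_per_group = 10,
                      mortality_schedule = list(WT = c(2L, 0L, 0L, 1L, 0L),
                                                TG = c(0L, 1L, 0L, 2L, 1L)),
                      rng_seed = 3)
  co <- generate_cohort(cfg)
  for (an in co) {
    expect_identical(an$ages_alive,
                     cfg$ages_months[seq_along(an$ages_alive)])
    expect_identical(names(an$weight_by_age), as.character(an$ages_alive))
  }
  expect_false(anyDuplicated(vapply(co, `[[`, "", "animal_id")) > 0)
})

test_that("zero mortality keeps every animal alive at all six ages", {
  co <- generate_cohort(tiny_config(seed = 5))
  expect_true(all(vapply(co, function(a) length(a$ages_alive), 0L) == 6L))
})

test_that("cohort generation is deterministic under a fixed seed", {
  cfg <- synth_config(n_per_group = 12,
                      mortality_schedule = list(WT = c(1L, 0L, 0L, 1L, 0L),
                                                TG = c(0L, 1L, 1L, 0L, 1L)),
                      rng_seed = 42)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
})

test_that("a mortality schedule exceeding the cohort size is rejected", {
  expect_error(
    synth_config(n_per_group = 5,
                 mortality_schedule = list(WT = c(4L, 0L, 0L, 2L, 1L),
                                           TG = c(1L, 1L, 2L, 4L, 5L))),
    "exceeds cohort size")
})

test_that("maturity factor is a linear ramp in weeks with hard anchors", {
  cfg <- synth_config()
  expect_equal(maturity_factor(12, cfg), 1.0)
  expect_equal(maturity_factor(0.9, cfg), 0.0)   # 3.9 weeks < 4-week onset
  mid_months <- ((4 + 15) / 2) / 4.345
  expect_equal(maturity_factor(mid_months, cfg), 0.5)
  ages <- seq(0, 14, by = 0.25)
  expect_true(all(diff(maturity_factor(ages, cfg)) >= 0))
  expect_error(maturity_factor(-1, cfg), "non-negative")
})

test_that("per-age weights follow the configured normal distributions", {
  cfg <- synth_config(n_per_group = 300,
                      mortality_schedule = list(WT = integer(5),
                                                TG = integer(5)),
                      rng_seed = 8)
  co <- generate_cohort(cfg)
  w1 <- vapply(co, function(a) a$weight_by_age[["1"]], 0)
  expect_equal(mean(w1), 14.9, tolerance = 0.05)
  expect_equal(sd(w1), 2.6, tolerance = 0.1)
})

test_that("cell-count mode reproduces a printed acquisition design exactly", {
  tab <- rbind(
    data.frame(group = "WT", eye = "OD", age = c(1, 2, 3, 4, 8, 12),
               n = c(53, 50, 48, 53, 44, 38)),
    data.frame(group = "WT", eye = "OS", age = c(1, 2, 3, 4, 8, 12),
               n = c(50, 51, 41, 52, 47, 36)),
    data.frame(group = "TG", eye = "OD", age = c(1, 2, 3, 4, 8, 12),
               n = c(44, 51, 52, 49, 46, 40)),
    data.frame(group = "TG", eye = "OS", age = c(1, 2, 3, 4, 8, 12),
               n = c(52, 52, 54, 52, 46, 43)))
  cfg <- synth_config(cell_counts = tab, rng_seed = 2)
  man <- cohort_manifest(generate_cohort(cfg), cfg)
  got <- aggregate(rep(1L, nrow(man)),
                   by = man[, c("group", "eye", "age")], FUN = sum)
  merged <- merge(tab, got, by = c("group", "eye", "age"))
  expect_equal(merged$x, merged$n)
  expect_equal(nrow(man), 1144L)
})

test_that("asking for more acquisitions than exist in a cell errors", {
  cfg <- tiny_config(cell_counts = data.frame(group = "WT", eye = "OD",
                                              age = 3, n = 99))
  expect_error(cohort_manifest(generate_cohort(cfg), cfg), "only")
})

test_that("generated boundaries are monotone and in range across seeds", {
  for (s in 1:5) {
    cfg <- tiny_config(seed = s, boundary_jitter = 3)
    co <- generate_cohort(cfg)
    gen <- generate_volume(co[[1]], 4, "OS", cfg)
    b <- gen$seg$boundaries
    for (k in 1:5) expect_true(all(b[, , k + 1] >= b[, , k]))
    expect_true(all(b >= 0 & b <= cfg$volume_shape[3]))
    expect_true(all(is.finite(gen$volume$intensities)))
    expect_true(all(gen$volume$intensities >= 0))
  }
})

test_that("group label has no effect on generation when effect size is zero", {
  cfg <- tiny_config(seed = 9, effect_size = 0)
  co <- generate_cohort(cfg)
  wt <- Filter(function(a) a$group == "WT", co)[[1]]
  tg <- Filter(function(a) a$group == "TG", co)[[1]]
  g_wt <- generate_volume(wt, 8, "OD", cfg, seed = 123)
  g_tg <- generate_volume(tg, 8, "OD", cfg, seed = 123)
  expect_identical(g_wt$volume$intensities, g_tg$volume$intensities)
  expect_identical(g_wt$seg$boundaries, g_tg$seg$boundaries)
})

test_that("noise-free flat-layer volumes project exactly to the baselines", {
  cfg <- tiny_config(seed = 4, noise_sd = 0, texture_amp = 0,
                     boundary_jitter = 0, effect_size = 0)
  co <- generate_cohort(cfg)
  gen <- generate_volume(co[[1]], 3, "OD", cfg)
  for (l in RETINAL_LAYERS) {
    mv <- compute_mvf(gen$volume, gen$seg, l)
    expect_true(all(mv$pixels == cfg$baseline_intensity[[l]]),
                info = l)
  }
  # planted effect adds exactly effect * ramp * field on affected layers:
  # with full maturity the TG / WT pixel difference is nonzero only there
  cfg2 <- tiny_config(seed = 4, noise_sd = 0, texture_amp = 0,
                      boundary_jitter = 0, effect_size = 25,
                      affected_layers = "OPL",
                      maturity_onset_weeks = 0, maturity_full_weeks = 0)
  co2 <- generate_cohort(cfg2)
  tg <- Filter(function(a) a$group == "TG", co2)[[1]]
  gen2 <- generate_volume(tg, 3, "OD", cfg2, seed = 77)
  mv_opl <- compute_mvf(gen2$volume, gen2$seg, "OPL")$pixels
  mv_ipl <- compute_mvf(gen2$volume, gen2$seg, "IPL")$pixels
  expect_true(all(mv_ipl == cfg2$baseline_intensity[["IPL"]]))
  expect_gt(sd(mv_opl), 0)
  expect_equal(mean(abs(mv_opl - cfg2$baseline_intensity[["OPL"]])) > 0, TRUE)
})

test_that("requesting a volume after an animal's death errors", {
  cfg <- synth_config(n_per_group = 2, ages_months = c(1, 2, 3),
                      mortality_schedule = list(WT = c(2L, 0L),
                                                TG = c(0L, 0L)),
                      rng_seed = 1)
  co <- generate_cohort(cfg)
  wt <- Filter(function(a) a$group == "WT", co)[[1]]
  expect_error(generate_volume(wt, 3, "OD", cfg), "not alive")
})

test_that("a null planted effect is statistically invisible in mean MVF intensity", {
  pvals <- vapply(1:30, function(s) {
    cfg <- synth_config(n_per_group = 10, ages_months = 3,
                        mortality_schedule = list(WT = integer(0),
                                                  TG = integer(0)),
                        effect_size = 0, volume_shape = c(8L, 12L, 32L),
                        rng_seed = 1000 + s)
    co <- generate_cohort(cfg)
    means <- vapply(co, function(an) {
      gen <- generate_volume(an, 3, "OD", cfg)
      mean(compute_mvf(gen$volume, gen$seg, "INL")$pixels)
    }, 0)
    groups <- vapply(co, `[[`, "", "group")
    t.test(means[groups == "WT"], means[groups == "TG"])$p.value
  }, 0)
  # nominal-rate rejections only: with 30 tests at alpha = 0.05, seeing
  # more than 6 rejections would be wildly above the nominal rate
  expect_lte(sum(pvals < 0.05), 6L)
  expect_gt(mean(pvals), 0.2)
})
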