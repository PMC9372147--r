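test_that("CLAHE passes a constant image through and respects the range", {
  p <- normalize_params()
  const <- matrix(3.7, 32, 32)
  expect_identical(clahe(const, p), const)
  set.seed(12)
  for (i in 1:5) {
    img <- matrix(runif(64 * 64, min = -3, max = 9), 64, 64)
    out <- clahe(img, p)
    expect_gte(min(out), min(img) - 1e-12)
    expect_lte(max(out), max(img) + 1e-12)
    expect_identical(dim(out), dim(img))
  }
})

test_that("CLAHE rejects images smaller than the tile grid", {
  expect_error(clahe(matrix(1:12 / 12, 3, 4),
                     normalize_params(clahe_tiles = c(8, 8))),
               "smaller than")
})

test_that("single-tile CLAHE matches the brute-force clipped equalization oracle", {
  set.seed(21)
  p <- normalize_params(clahe_tiles = c(1, 1), clahe_clip = 0.01)
  for (i in 1:5) {
    img <- matrix(rnorm(48 * 40, 100, 20), 48, 40)
    expect_equal(clahe(img, p), brute_clipped_hist_eq(img, clip = 0.01),
                 tolerance = 1e-12)
  }
  # and with a much larger clip limit (weak clipping)
  p2 <- normalize_params(clahe_tiles = c(1, 1), clahe_clip = 0.2)
  img <- matrix(runif(30 * 30), 30, 30)
  expect_equal(clahe(img, p2), brute_clipped_hist_eq(img, clip = 0.2),
               tolerance = 1e-12)
})

test_that("the Gaussian LPF preserves constants and has unit-mass impulse response", {
  p <- normalize_params()
  const <- matrix(5, 40, 40)
  expect_equal(gaussian_lpf(const, p), const, tolerance = 1e-12)
  n <- 301L
  imp <- matrix(0, n, n)
  imp[151, 151] <- 1
  resp <- gaussian_lpf(imp, p)
  expect_equal(sum(resp), 1, tolerance = 1e-9)
  # centre patch equals the separable kernel outer product
  g <- dnorm(seq(-60, 60), sd = 25); g <- g / sum(g)
  expect_equal(resp[91:211, 91:211], outer(g, g), tolerance = 1e-12)
})

test_that("z-scoring a 2x2 image matches the hand-computed mapping", {
  img <- matrix(c(1, 2, 3, 4), 2, 2)
  # mean 2.5, sample sd sqrt(5/3); out = 128 + 8 * (x - 2.5) / sd
  out <- zscore_scale(img, scale = 8, offset = 128)
  expect_equal(as.vector(out),
               c(118.704840, 124.901613, 131.098387, 137.295160),
               tolerance = 1e-6)
})

test_that("the full chain yields mean 128 and sd 8 on non-degenerate images", {
  set.seed(5)
  p <- normalize_params()
  for (i in 1:4) {
    img <- matrix(runif(64 * 48, 0, 255), 64, 48)
    out <- normalize_mvf(img, p)
    expect_equal(mean(out), 128, tolerance = 1e-6)
    expect_equal(sd(out), 8, tolerance = 1e-6)
  }
})

test_that("a constant input collapses to an all-128 image with a warning", {
  expect_warning(out <- normalize_mvf(matrix(42, 20, 20)), "degenerate")
  expect_true(all(out == 128))
})

test_that("normalization is idempotent in its moment contract and deterministic", {
  set.seed(99)
  img <- matrix(rnorm(50 * 50, 100, 15), 50, 50)
  p <- normalize_params()
  out1 <- normalize_mvf(img, p)
  out2 <- normalize_mvf(img, p)
  expect_identical(out1, out2)
  again <- zscore_scale(out1)
  expect_equal(mean(again), 128, tolerance = 1e-9)
  expect_equal(sd(again), 8, tolerance = 1e-9)
})

test_that("the chain removes a planted global intensity offset between groups", {
  set.seed(14)
  p <- normalize_params()
  wt <- lapply(1:6, function(i) matrix(rnorm(40 * 40, 100, 12), 40, 40))
  tg <- lapply(wt, function(m) m + 60)   # large global offset
  wt_n <- vapply(wt, function(m) mean(normalize_mvf(m, p)), 0)
  tg_n <- vapply(tg, function(m) mean(normalize_mvf(m, p)), 0)
  expect_lt(abs(mean(wt_n) - mean(tg_n)), 1e-6)
})

test_that("augmentation returns a vertical flip and a 90/270 rotation", {
  img <- matrix(1:20, 4, 5)
  a <- augment(img, seed = 7)
  expect_identical(a$vflip, img[4:1, ])
  expect_identical(a$vflip[4:1, ], img)           # flip is an involution
  expect_true(attr(a$rotation, "angle") %in% c(90, 270))
  expect_identical(dim(a$rotation), c(5L, 4L))
  # rotating four times by the same angle restores the original
  r <- img
  for (i in 1:4) r <- rotate90(r, clockwise = TRUE)
  expect_identical(r, img)
})

test_that("rotation angles are drawn uniformly", {
  img <- matrix(1:4, 2, 2)
  angles <- with(list(), {
    set.seed(123)
    vapply(1:10000, function(i) attr(augment(img)$rotation, "angle"), 0)
  })
  expect_equal(mean(angles == 90), 0.5, tolerance = 0.02)
})
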