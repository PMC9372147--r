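# Small separable image sets: the transgenic class carries amplified pixel
# contrast (texture energy), a difference the pooled convolutional features
# reflect directly.
make_image_set <- function(n_per_class, amp, seed, nr = 24, nc = 32) {
  set.seed(seed)
  mk <- function(a) {
    lapply(seq_len(n_per_class), function(i) {
      matrix(rnorm(nr * nc, 128, 8 * (1 + a)), nr, nc)
    })
  }
  list(images = c(mk(0), mk(amp)),
       labels = rep(c("WT", "TG"), each = n_per_class))
}

test_that("head-only training leaves every backbone parameter untouched", {
  tr <- make_image_set(20, 10, seed = 1)
  va <- make_image_set(6, 10, seed = 2)
  cfg <- classifier_config(epochs = 5, seed = 3)
  before <- backbone_checksum(init_backbone(cfg))
  m <- train_layer_model(tr, va, cfg)
  expect_identical(backbone_checksum(m), before)
})

test_that("fine-tuning updates only the last block", {
  tr <- make_image_set(12, 10, seed = 4)
  va <- make_image_set(4, 10, seed = 5)
  cfg <- classifier_config(epochs = 3, seed = 6,
                           trainable_scope = "head_plus_last_block")
  bb0 <- init_backbone(cfg)
  m <- train_layer_model(tr, va, cfg)
  expect_identical(backbone_checksum(m, blocks = 1:3),
                   backbone_checksum(bb0, blocks = 1:3))
  expect_false(isTRUE(all.equal(backbone_checksum(m, blocks = 4),
                                backbone_checksum(bb0, blocks = 4))))
})

test_that("training is deterministic and layer runs share no state", {
  tr <- make_image_set(10, 12, seed = 7)
  va <- make_image_set(4, 12, seed = 8)
  cfg <- classifier_config(epochs = 4, seed = 9)
  m1 <- train_layer_model(tr, va, cfg, layer = "IPL")
  # interleave an unrelated training run, then repeat
  other <- train_layer_model(make_image_set(8, 5, seed = 20),
                             make_image_set(4, 5, seed = 21),
                             classifier_config(epochs = 2, seed = 33))
  m2 <- train_layer_model(tr, va, cfg, layer = "IPL")
  expect_identical(m1$w, m2$w)
  expect_identical(m1$b, m2$b)
  expect_identical(m1$val_loss, m2$val_loss)
})

test_that("a clearly separable planted texture is learned", {
  tr <- make_image_set(40, 15, seed = 10)
  va <- make_image_set(10, 15, seed = 11)
  te <- make_image_set(15, 15, seed = 12)
  m <- train_layer_model(tr, va, classifier_config(epochs = 30,
                                                   learning_rate = 1e-2,
                                                   seed = 13))
  pr <- predict_mvf(m, te$images)
  expect_gte(mean(pr$label == te$labels), 0.8)
  expect_true(all(pr$probability >= 0 & pr$probability <= 1))
})

test_that("single-class training sets are rejected", {
  tr <- make_image_set(6, 10, seed = 14)
  tr$labels <- rep("WT", length(tr$labels))
  va <- make_image_set(2, 10, seed = 15)
  expect_error(train_layer_model(tr, va, classifier_config(epochs = 2)),
               "both classes")
})

test_that("prediction applies the tie-goes-positive threshold rule", {
  tr <- make_image_set(8, 12, seed = 16)
  va <- make_image_set(3, 12, seed = 17)
  m <- train_layer_model(tr, va, classifier_config(epochs = 2, seed = 18))
  pr <- predict_mvf(m, tr$images[[1]], threshold = 0)
  expect_identical(pr$label, "TG")   # probability >= 0 always
  p <- pr$probability
  pr2 <- predict_mvf(m, tr$images[[1]], threshold = p)
  expect_identical(pr2$label, "TG")  # exactly at threshold -> positive
  pr3 <- predict_mvf(m, tr$images[[1]], threshold = p + 1e-9)
  expect_identical(pr3$label, "WT")
})

test_that("batch predictions equal concatenated single-image predictions", {
  tr <- make_image_set(8, 12, seed = 19)
  va <- make_image_set(3, 12, seed = 22)
  m <- train_layer_model(tr, va, classifier_config(epochs = 2, seed = 23))
  batch <- predict_mvf(m, va$images)
  singles <- do.call(rbind, lapply(va$images, function(i) predict_mvf(m, i)))
  expect_equal(batch$probability, singles$probability)
  expect_identical(batch$label, singles$label)
})

test_that("images of the wrong size are rejected at prediction", {
  tr <- make_image_set(8, 12, seed = 24)
  va <- make_image_set(3, 12, seed = 25)
  m <- train_layer_model(tr, va, classifier_config(epochs = 2, seed = 26))
  expect_error(predict_mvf(m, matrix(0, 10, 10)), "does not match")
})
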