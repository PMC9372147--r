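#' Configuration of the per-layer convolutional classifier
#'
#' The classifier follows a transfer-learning design: a convolutional
#' feature-extractor backbone whose parameters are fixed at initialization,
#' a global average pooling layer, and a single fully-connected unit with a
#' sigmoid activation producing the probability of the transgenic class.
#' With `trainable_scope = "head_only"` (the default) training updates only
#' the head; `"head_plus_last_block"` additionally fine-tunes the last
#' convolutional block by backpropagation, at a lower learning rate.
#'
#' @param backbone Only `"small_cnn"` is provided: four 3x3 convolution
#'   blocks (ReLU, 2x2 max pooling after the first three) with
#'   `channels` feature maps, parameters drawn once from a seeded
#'   He-scaled normal distribution.
#' @param trainable_scope `"head_only"` or `"head_plus_last_block"`.
#' @param channels Feature maps per block.
#' @param epochs Maximum training epochs.
#' @param batch_size Mini-batch size.
#' @param learning_rate Adam learning rate for the head.
#' @param finetune_lr Adam learning rate for the last block when
#'   fine-tuning.
#' @param patience Early-stopping patience (epochs without validation-loss
#'   improvement); the returned model is the state at best validation loss.
#' @param l2 L2 penalty on the head weights.
#' @param threshold Decision threshold on the transgenic probability; ties
#'   go to the positive (transgenic) class.
#' @param input_center,input_scale Affine input standardization applied
#'   before the first convolution (defaults match the normalization chain's
#'   output moments of 128 and 8).
#' @param seed Integer seed controlling backbone initialization and batch
#'   shuffling.
#' @return Object of class `classifier_config`.
#' @export
classifier_config <- function(backbone = "small_cnn",
                              trainable_scope = c("head_only",
                                                  "head_plus_last_block"),
                              channels = c(8L, 16L, 32L, 64L),
                              epochs = 30L,
                              batch_size = 32L,
                              learning_rate = 1e-3,
                              finetune_lr = 1e-4,
                              patience = 5L,
                              l2 = 1e-4,
                              threshold = 0.5,
                              input_center = 128,
                              input_scale = 8,
                              seed = 1L) {
  if (!identical(backbone, "small_cnn")) {
    stop_bad("unsupported backbone '%s'", backbone)
  }
  trainable_scope <- match.arg(trainable_scope)
  structure(list(backbone = backbone, trainable_scope = trainable_scope,
                 channels = as.integer(channels), epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, finetune_lr = finetune_lr,
                 patience = as.integer(patience), l2 = l2,
                 threshold = threshold, input_center = input_center,
                 input_scale = input_scale, seed = as.integer(seed)),
            class = "classifier_config")
}

# ---- backbone primitives -------------------------------------------------

# 3x3 same-padding (zero) convolution; x (h,w,cin), W (3,3,cin,cout).
conv3x3 <- function(x, W, b = NULL) {
  h <- dim(x)[1]; w <- dim(x)[2]; cin <- dim(x)[3]; cout <- dim(W)[4]
  xp <- array(0, c(h + 2L, w + 2L, cin))
  xp[2:(h + 1L), 2:(w + 1L), ] <- x
  out <- matrix(0, h * w, cout)
  for (dy in 1:3) {
    for (dx in 1:3) {
      slab <- xp[dy:(dy + h - 1L), dx:(dx + w - 1L), , drop = FALSE]
      out <- out + matrix(slab, h * w, cin) %*% matrix(W[dy, dx, , ], cin, cout)
    }
  }
  if (!is.null(b)) out <- sweep(out, 2L, b, `+`)
  array(out, c(h, w, cout))
}

maxpool2 <- function(x) {
  h <- dim(x)[1] %/% 2L * 2L
  w <- dim(x)[2] %/% 2L * 2L
  x <- x[seq_len(h), seq_len(w), , drop = FALSE]
  pmax(x[seq(1L, h, 2L), seq(1L, w, 2L), , drop = FALSE],
       x[seq(2L, h, 2L), seq(1L, w, 2L), , drop = FALSE],
       x[seq(1L, h, 2L), seq(2L, w, 2L), , drop = FALSE],
       x[seq(2L, h, 2L), seq(2L, w, 2L), , drop = FALSE])
}

global_avg_pool <- function(x) {
  apply(x, 3L, mean)
}

# Fixed He-initialized backbone: list of blocks, each list(W, b).
init_backbone <- function(config, in_channels = 1L) {
  with_rng(config$seed, {
    cin <- in_channels
    lapply(config$channels, function(cout) {
      W <- array(stats::rnorm(9L * cin * cout, 0, sqrt(2 / (9 * cin))),
                 c(3L, 3L, cin, cout))
      blk <- list(W = W, b = numeric(cout))
      cin <<- cout
      blk
    })
  })
}

# Run blocks 1..n_blocks; pooling after every block except the last one of
# the full network.
backbone_forward <- function(img, backbone, config, upto = length(backbone)) {
  x <- array((img - config$input_center) / config$input_scale,
             c(nrow(img), ncol(img), 1L))
  nb <- length(backbone)
  for (i in seq_len(upto)) {
    x <- conv3x3(x, backbone[[i]]$W, backbone[[i]]$b)
    x <- pmax(x, 0)
    if (i < nb) x <- maxpool2(x)
  }
  x
}

#' Checksum of backbone parameters
#'
#' Order-sensitive digest of every backbone weight, used to assert that the
#' frozen scope really is untouched by training.
#'
#' @param backbone A backbone (list of blocks) or a trained model.
#' @param blocks Which blocks to include (default all).
#' @return A single numeric digest.
#' @export
backbone_checksum <- function(backbone, blocks = NULL) {
  if (!is.null(backbone$backbone)) backbone <- backbone$backbone
  if (is.null(blocks)) blocks <- seq_along(backbone)
  sum(vapply(backbone[blocks], function(blk) {
    v <- c(as.vector(blk$W), blk$b)
    sum(v * seq_along(v))
  }, numeric(1)))
}

sigmoid <- function(z) 1 / (1 + exp(-pmin(pmax(z, -30), 30)))

bce_loss <- function(p, y) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

adam_step <- function(state, grad, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^t)
  vhat <- state$v / (1 - beta2^t)
  state$delta <- -lr * mhat / (sqrt(vhat) + eps)
  state
}

labels_to_binary <- function(labels) {
  if (is.numeric(labels)) {
    y <- as.numeric(labels)
  } else {
    y <- as.numeric(labels %in% c("TG", "3xTg-AD", "1"))
  }
  if (!all(y %in% c(0, 1))) stop_bad("labels must be WT/TG (or 0/1)")
  y
}

#' Train the classifier for one retinal layer
#'
#' Trains a binary classifier (wild type vs transgenic) on normalized MVF
#' images of a single retinal layer. The backbone is initialized from
#' `config$seed` and — under the default `head_only` scope — never updated;
#' only the global-average-pooled features feed a sigmoid unit trained with
#' Adam on cross-entropy loss. Early stopping monitors validation loss and
#' the returned model is the state at the best validation epoch. An
#' independent call with the same inputs and seed reproduces the model
#' exactly; models for different layers share no state.
#'
#' @param train,val Lists with elements `images` (list of 2-D matrices, all
#'   the same size) and `labels` (`"WT"`/`"TG"` or 0/1, positive class =
#'   transgenic).
#' @param config A [classifier_config()].
#' @param layer Optional layer identifier stored in the model.
#' @return Object of class `layer_model`.
#' @export
train_layer_model <- function(train, val, config = classifier_config(),
                              layer = NULL) {
  y_tr <- labels_to_binary(train$labels)
  y_va <- labels_to_binary(val$labels)
  if (length(unique(y_tr)) < 2L) {
    stop_bad("training set must contain both classes")
  }
  if (length(train$images) != length(y_tr) ||
      length(val$images) != length(y_va)) {
    stop_bad("images and labels differ in length")
  }
  input_dim <- dim(train$images[[1]])
  backbone <- init_backbone(config)
  finetune <- identical(config$trainable_scope, "head_plus_last_block")
  nb <- length(backbone)

  # cache the (frozen) input to the last block per image
  cache <- function(imgs) {
    lapply(imgs, backbone_forward, backbone = backbone, config = config,
           upto = nb - 1L)
  }
  h_tr <- cache(train$images)
  h_va <- cache(val$images)

  last_feats <- function(h, blk) {
    z <- conv3x3(h, blk$W, blk$b)
    global_avg_pool(pmax(z, 0))
  }
  feats_all <- function(hs, blk) {
    t(vapply(hs, last_feats, numeric(utils::tail(config$channels, 1)),
             blk = blk))
  }

  blk <- backbone[[nb]]
  X_tr <- feats_all(h_tr, blk)
  X_va <- feats_all(h_va, blk)
  mu <- colMeans(X_tr)
  sdv <- apply(X_tr, 2L, stats::sd)
  sdv[!is.finite(sdv) | sdv == 0] <- 1

  nf <- ncol(X_tr)
  # fresh dense head: small random init so gradients reach the fine-tuned
  # block from the first step
  w <- with_rng(config$seed + 2L, stats::rnorm(nf, 0, 0.01))
  b0 <- 0
  st_w <- list(m = numeric(nf), v = numeric(nf))
  st_b <- list(m = 0, v = 0)
  st_W4 <- list(m = array(0, dim(blk$W)), v = array(0, dim(blk$W)))
  st_b4 <- list(m = numeric(length(blk$b)), v = numeric(length(blk$b)))

  n <- length(y_tr)
  best <- list(loss = Inf)
  stale <- 0L
  t_step <- 0L

  with_rng(config$seed + 1L, {
    for (epoch in seq_len(config$epochs)) {
      idx <- sample.int(n)
      for (start in seq(1L, n, by = config$batch_size)) {
        bidx <- idx[start:min(start + config$batch_size - 1L, n)]
        t_step <- t_step + 1L
        if (finetune) {
          Zb <- lapply(h_tr[bidx], function(h) conv3x3(h, blk$W, blk$b))
          Fb <- t(vapply(Zb, function(z) global_avg_pool(pmax(z, 0)),
                         numeric(nf)))
        } else {
          Fb <- X_tr[bidx, , drop = FALSE]
        }
        Fs <- sweep(sweep(Fb, 2L, mu), 2L, sdv, `/`)
        p <- sigmoid(drop(Fs %*% w) + b0)
        dlogit <- (p - y_tr[bidx]) / length(bidx)
        gw <- drop(crossprod(Fs, dlogit)) + 2 * config$l2 * w
        gb <- sum(dlogit)
        st_w <- adam_step(st_w, gw, config$learning_rate, t_step)
        st_b <- adam_step(st_b, gb, config$learning_rate, t_step)
        if (finetune) {
          gW4 <- array(0, dim(blk$W))
          gb4 <- numeric(length(blk$b))
          dF <- outer(dlogit, w / sdv)        # gradient wrt raw features
          for (m in seq_along(bidx)) {
            z <- Zb[[m]]
            hw <- dim(z)[1] * dim(z)[2]
            dz <- array(rep(dF[m, ] / hw, each = hw), dim(z)) * (z > 0)
            h <- h_tr[[bidx[m]]]
            hp <- array(0, dim(h) + c(2L, 2L, 0L))
            hp[2:(dim(h)[1] + 1L), 2:(dim(h)[2] + 1L), ] <- h
            dz_mat <- matrix(dz, hw, dim(z)[3])
            for (dy in 1:3) {
              for (dx in 1:3) {
                slab <- hp[dy:(dy + dim(h)[1] - 1L),
                           dx:(dx + dim(h)[2] - 1L), , drop = FALSE]
                gW4[dy, dx, , ] <- gW4[dy, dx, , ] +
                  crossprod(matrix(slab, hw, dim(h)[3]), dz_mat)
              }
            }
            gb4 <- gb4 + colSums(dz_mat)
          }
          st_W4 <- adam_step(st_W4, gW4, config$finetune_lr, t_step)
          st_b4 <- adam_step(st_b4, gb4, config$finetune_lr, t_step)
          blk$W <- blk$W + st_W4$delta
          blk$b <- blk$b + st_b4$delta
        }
        w <- w + st_w$delta
        b0 <- b0 + st_b$delta
      }
      Xv <- if (finetune) feats_all(h_va, blk) else X_va
      Xvs <- sweep(sweep(Xv, 2L, mu), 2L, sdv, `/`)
      val_loss <- bce_loss(sigmoid(drop(Xvs %*% w) + b0), y_va)
      if (val_loss < best$loss - 1e-9) {
        best <- list(loss = val_loss, w = w, b = b0, blk = blk,
                     epoch = epoch)
        stale <- 0L
      } else {
        stale <- stale + 1L
        if (stale >= config$patience) break
      }
    }
  })

  backbone[[nb]] <- best$blk
  structure(list(config = config, layer = layer, backbone = backbone,
                 feat_mu = mu, feat_sd = sdv, w = best$w, b = best$b,
                 input_dim = input_dim, best_epoch = best$epoch,
                 val_loss = best$loss),
            class = "layer_model")
}

#' Predict group membership for MVF images
#'
#' Runs the trained model on one image or a list of images, returning the
#' transgenic-class probability and the thresholded label. Predictions on a
#' batch equal the concatenation of single-image predictions; a probability
#' exactly at the threshold classifies as transgenic.
#'
#' @param model A [train_layer_model()] result.
#' @param images A 2-D matrix or a list of matrices matching the training
#'   image size.
#' @param threshold Decision threshold; defaults to the training
#'   configuration's.
#' @return Data frame with columns `probability` and `label`
#'   (`"WT"`/`"TG"`).
#' @export
predict_mvf <- function(model, images, threshold = NULL) {
  threshold <- threshold %||% model$config$threshold
  if (is.matrix(images)) images <- list(images)
  probs <- vapply(images, function(img) {
    if (!identical(dim(img), as.integer(model$input_dim)) &&
        !identical(as.integer(dim(img)), as.integer(model$input_dim))) {
      stop_bad("image size %s does not match model input %s",
               paste(dim(img), collapse = "x"),
               paste(model$input_dim, collapse = "x"))
    }
    a <- backbone_forward(img, model$backbone, model$config)
    f <- (global_avg_pool(a) - model$feat_mu) / model$feat_sd
    sigmoid(sum(f * model$w) + model$b)
  }, numeric(1))
  data.frame(probability = probs,
             label = ifelse(probs >= threshold, "TG", "WT"),
             stringsAsFactors = FALSE)
}

#' @export
print.layer_model <- function(x, ...) {
  cat(sprintf("layer_model (%s, %s)%s: best epoch %d, val loss %.4f\n",
              x$config$backbone, x$config$trainable_scope,
              if (is.null(x$layer)) "" else sprintf(" for %s", x$layer),
              x$best_epoch, x$val_loss))
  invisible(x)
}
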