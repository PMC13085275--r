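# Training: SGD with momentum, categorical cross-entropy, on-the-fly geometric
# augmentation of training mini-batches only.

#' Training configuration
#'
#' Defaults follow the study's fixed fine-tuning recipe: mini-batch 5, 50
#' epochs, learning rate 0.001 with no schedule, SGD with momentum 0.9 and L2
#' weight decay 1e-4.
#'
#' @param minibatch mini-batch size.
#' @param epochs number of epochs.
#' @param learning_rate fixed learning rate (no scheduling).
#' @param momentum SGDM momentum coefficient.
#' @param weight_decay L2 weight decay.
#' @param validation_frequency record a history row every this many
#'   iterations (dataset-size dependent; free to choose).
#' @param seed integer seed controlling shuffling and augmentation draws.
#' @return An object of class `training_config`.
#' @export
training_config <- function(minibatch = 5L, epochs = 50L, learning_rate = 0.001,
                            momentum = 0.9, weight_decay = 1e-4,
                            validation_frequency = 10L, seed = 1L) {
  vals <- c(minibatch, epochs, learning_rate, momentum, weight_decay,
            validation_frequency)
  stop_if_not(all(vals > 0), "training_config values must all be positive")
  structure(list(minibatch = as.integer(minibatch), epochs = as.integer(epochs),
                 learning_rate = learning_rate, momentum = momentum,
                 weight_decay = weight_decay,
                 validation_frequency = as.integer(validation_frequency),
                 seed = as.integer(seed)),
            class = "training_config")
}

#' Geometric augmentation ranges
#'
#' The ranges mirror the study's policy: scaling 0.6-2.6, shearing within
#' +/-59 degrees, x/y translation within +/-46 px, rotation within +/-90
#' degrees, plus random x/y axis reflections. All operations are purely
#' geometric; colour channels are never touched.
#'
#' @param scale scaling factor range.
#' @param shear_deg shear angle range (degrees).
#' @param reflect_xy x/y translation range in pixels (the policy's
#'   "reverse in x and y" scale; axis flips are the Bernoulli `reflect`).
#' @param rotation_deg rotation range (degrees).
#' @param reflect draw random x/y axis reflections (Bernoulli 1/2 each)?
#' @return An object of class `augmentation_ranges`.
#' @export
augmentation_ranges <- function(scale = c(0.6, 2.6), shear_deg = c(-59, 59),
                                reflect_xy = c(-46, 46),
                                rotation_deg = c(-90, 90), reflect = TRUE) {
  for (r in list(scale, shear_deg, reflect_xy, rotation_deg)) {
    stop_if_not(length(r) == 2 && r[1] <= r[2], "each range needs low <= high")
  }
  structure(list(scale = scale, shear_deg = shear_deg, reflect_xy = reflect_xy,
                 rotation_deg = rotation_deg, reflect = isTRUE(reflect)),
            class = "augmentation_ranges")
}

#' Identity augmentation (all ranges collapsed)
#' @return An `augmentation_ranges` object that leaves images unchanged.
#' @export
identity_ranges <- function() {
  augmentation_ranges(scale = c(1, 1), shear_deg = c(0, 0),
                      reflect_xy = c(0, 0), rotation_deg = c(0, 0),
                      reflect = FALSE)
}

# Reflective (mirror) index folding into [1, n].
reflect_index <- function(x, n) {
  if (n == 1) return(rep(1, length(x)))
  period <- 2 * (n - 1)
  x <- abs(x - 1) %% period
  ifelse(x > (n - 1), period - x, x) + 1
}

# Bilinear sampling of one channel plane at real-valued coords, reflective
# boundary.
bilinear_sample <- function(plane, ys, xs) {
  h <- nrow(plane); w <- ncol(plane)
  y0 <- floor(ys); x0 <- floor(xs)
  fy <- ys - y0; fx <- xs - x0
  iy0 <- reflect_index(y0, h); iy1 <- reflect_index(y0 + 1, h)
  ix0 <- reflect_index(x0, w); ix1 <- reflect_index(x0 + 1, w)
  idx <- function(iy, ix) plane[cbind(iy, ix)]
  (1 - fy) * (1 - fx) * idx(iy0, ix0) + (1 - fy) * fx * idx(iy0, ix1) +
    fy * (1 - fx) * idx(iy1, ix0) + fy * fx * idx(iy1, ix1)
}

# Apply an affine transform (about the image centre) to an RGB image with
# bilinear interpolation and reflective out-of-frame padding.
warp_affine <- function(img, scale = 1, shear_deg = 0, rot_deg = 0,
                        tx = 0, ty = 0, flip_x = FALSE, flip_y = FALSE) {
  h <- dim(img)[1]; w <- dim(img)[2]
  th <- rot_deg * pi / 180; sh <- tan(shear_deg * pi / 180)
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  Sh <- matrix(c(1, 0, sh, 1), 2, 2)
  Sc <- diag(c(scale * ifelse(flip_x, -1, 1), scale * ifelse(flip_y, -1, 1)))
  A <- R %*% Sh %*% Sc                          # forward (x, y) map
  Ainv <- solve(A)
  cx <- (w + 1) / 2; cy <- (h + 1) / 2
  xo <- matrix(rep(seq_len(w), each = h), h, w) - cx - tx
  yo <- matrix(rep(seq_len(h), times = w), h, w) - cy - ty
  xs <- Ainv[1, 1] * xo + Ainv[1, 2] * yo + cx
  ys <- Ainv[2, 1] * xo + Ainv[2, 2] * yo + cy
  out <- array(0, dim = dim(img))
  for (ch in seq_len(dim(img)[3])) {
    out[, , ch] <- matrix(bilinear_sample(img[, , ch], as.vector(ys),
                                          as.vector(xs)), h, w)
  }
  out
}

#' Randomly augment an image
#'
#' Draws scale, shear, translation and rotation uniformly from the configured
#' ranges (plus Bernoulli axis reflections if enabled) and applies the
#' composed affine transform about the image centre. Output size is
#' preserved; out-of-frame pixels are reflect-padded; colour channels are
#' untouched. With all ranges collapsed to identity values the image is
#' returned unchanged.
#'
#' @param img `H x W x 3` array in `[0, 1]`.
#' @param ranges an [augmentation_ranges()].
#' @param seed optional seed; `NULL` draws from the current RNG stream.
#' @return The augmented image.
#' @export
augment_image <- function(img, ranges = augmentation_ranges(), seed = NULL) {
  draw <- function() {
    u <- function(r) if (r[1] == r[2]) r[1] else stats::runif(1, r[1], r[2])
    warp_affine(img,
                scale = u(ranges$scale),
                shear_deg = u(ranges$shear_deg),
                rot_deg = u(ranges$rotation_deg),
                tx = u(ranges$reflect_xy), ty = u(ranges$reflect_xy),
                flip_x = ranges$reflect && stats::runif(1) < 0.5,
                flip_y = ranges$reflect && stats::runif(1) < 0.5)
  }
  identity_cfg <- all(ranges$scale == 1) && all(ranges$shear_deg == 0) &&
    all(ranges$reflect_xy == 0) && all(ranges$rotation_deg == 0) &&
    !ranges$reflect
  if (identity_cfg) return(img)
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

# ---- SGDM -------------------------------------------------------------------

zero_like_grads <- function(model) {
  g <- list(layers = vector("list", length(model$layers)))
  for (i in seq_along(model$layers)) {
    ly <- model$layers[[i]]
    if (ly$type == "conv") {
      g$layers[[i]] <- list(dW = ly$W * 0, db = ly$b * 0)
    }
  }
  g$att <- lapply(model$att_w, function(m) m * 0)
  g$fc <- list(dW = model$fc$W * 0, db = model$fc$b * 0)
  g
}

add_grads <- function(acc, g) {
  for (i in seq_along(acc$layers)) {
    if (!is.null(acc$layers[[i]])) {
      acc$layers[[i]]$dW <- acc$layers[[i]]$dW + g$layers[[i]]$dW
      acc$layers[[i]]$db <- acc$layers[[i]]$db + g$layers[[i]]$db
    }
  }
  acc$att$W_Q <- acc$att$W_Q + g$att$W_Q
  acc$att$W_K <- acc$att$W_K + g$att$W_K
  acc$att$W_V <- acc$att$W_V + g$att$W_V
  acc$att$W_O <- acc$att$W_O + g$att$W_O
  acc$fc$dW <- acc$fc$dW + g$fc$dW
  acc$fc$db <- acc$fc$db + g$fc$db
  acc
}

sgdm_step <- function(model, vel, grads, tcfg, batch_n) {
  lr <- tcfg$learning_rate; mom <- tcfg$momentum; wd <- tcfg$weight_decay
  upd <- function(w, v, g, decay = TRUE) {
    g <- g / batch_n + if (decay) wd * w else 0
    v <- mom * v - lr * g
    list(w = w + v, v = v)
  }
  for (i in seq_along(model$layers)) {
    if (model$layers[[i]]$type == "conv") {
      r <- upd(model$layers[[i]]$W, vel$layers[[i]]$dW, grads$layers[[i]]$dW)
      model$layers[[i]]$W <- r$w; vel$layers[[i]]$dW <- r$v
      r <- upd(model$layers[[i]]$b, vel$layers[[i]]$db, grads$layers[[i]]$db,
               decay = FALSE)
      model$layers[[i]]$b <- r$w; vel$layers[[i]]$db <- r$v
    }
  }
  for (nm in c("W_Q", "W_K", "W_V", "W_O")) {
    r <- upd(model$att_w[[nm]], vel$att[[nm]], grads$att[[nm]])
    model$att_w[[nm]] <- r$w; vel$att[[nm]] <- r$v
  }
  r <- upd(model$fc$W, vel$fc$dW, grads$fc$dW)
  model$fc$W <- r$w; vel$fc$dW <- r$v
  r <- upd(model$fc$b, vel$fc$db, grads$fc$db, decay = FALSE)
  model$fc$b <- r$w; vel$fc$db <- r$v
  list(model = model, vel = vel)
}

# Per-image forward + backward; returns loss, correctness and gradients.
train_step_one <- function(model, img, label) {
  sf <- stack_forward(model, img)
  hf <- head_forward(model, sf$map)
  probs <- as.numeric(softmax_rows(matrix(hf$logits, 1)))
  y <- numeric(model$n_classes); y[label + 1L] <- 1
  loss <- cross_entropy(y, probs)
  dlogits <- probs - y
  hb <- head_backward(model, hf, dlogits)
  stack_grads <- stack_backward(model, sf$caches, hb$dmap)
  list(loss = loss, correct = which.max(probs) - 1L == label,
       grads = list(layers = stack_grads,
                    att = list(W_Q = hb$dW_Q, W_K = hb$dW_K,
                               W_V = hb$dW_V, W_O = hb$dW_O),
                    fc = list(dW = hb$dW_fc, db = hb$db_fc)))
}

#' Train an attention-augmented CNN
#'
#' SGD with momentum at a fixed learning rate; categorical cross-entropy loss;
#' geometric augmentation applied on-the-fly to training mini-batches only
#' (validation images are never augmented). Deterministic given
#' `tcfg$seed`.
#'
#' @param model a [build_attention_model()] model.
#' @param images list of training images (`H x W x 3` arrays).
#' @param labels 0-based integer labels aligned with `images`; every class in
#'   `0..n_classes-1` must be present.
#' @param tcfg a [training_config()].
#' @param ranges an [augmentation_ranges()]; use [identity_ranges()] to
#'   disable augmentation.
#' @param val_images,val_labels optional held-out set evaluated every
#'   `validation_frequency` iterations.
#' @return A list with the trained `model`, a per-epoch `history` data frame
#'   (`epoch`, `loss`, `accuracy`) and an iteration-level `val_history`.
#' @export
train_model <- function(model, images, labels, tcfg = training_config(),
                        ranges = augmentation_ranges(),
                        val_images = NULL, val_labels = NULL) {
  stop_if_not(length(images) == length(labels), "images/labels length mismatch")
  present <- sort(unique(labels))
  missing_cls <- setdiff(seq_len(model$n_classes) - 1L, present)
  stop_if_not(length(missing_cls) == 0,
              paste("empty class(es):", paste(missing_cls, collapse = ", ")))
  n <- length(images)
  with_seed(tcfg$seed, {
    vel <- zero_like_grads(model)
    history <- data.frame(epoch = integer(0), loss = numeric(0),
                          accuracy = numeric(0))
    val_history <- data.frame(iteration = integer(0), loss = numeric(0),
                              val_accuracy = numeric(0))
    iter <- 0L
    for (ep in seq_len(tcfg$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; ep_correct <- 0L
      for (b0 in seq(1, n, by = tcfg$minibatch)) {
        idx <- ord[b0:min(b0 + tcfg$minibatch - 1L, n)]
        acc <- zero_like_grads(model)
        b_loss <- 0
        for (i in idx) {
          im <- augment_image(images[[i]], ranges)
          r <- train_step_one(model, im, labels[i])
          acc <- add_grads(acc, r$grads)
          b_loss <- b_loss + r$loss
          ep_correct <- ep_correct + r$correct
        }
        st <- sgdm_step(model, vel, acc, tcfg, length(idx))
        model <- st$model; vel <- st$vel
        ep_loss <- ep_loss + b_loss
        iter <- iter + 1L
        if (iter %% tcfg$validation_frequency == 0L) {
          va <- NA_real_
          if (!is.null(val_images)) {
            vp <- predict_model(model, val_images)
            va <- mean(max.col(vp) - 1L == val_labels)
          }
          val_history <- rbind(val_history,
                               data.frame(iteration = iter,
                                          loss = b_loss / length(idx),
                                          val_accuracy = va))
        }
      }
      history <- rbind(history,
                       data.frame(epoch = ep, loss = ep_loss / n,
                                  accuracy = ep_correct / n))
    }
    list(model = model, history = history, val_history = val_history)
  })
}
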