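# Lightweight CNN backbones with an inserted multi-head self-attention module.
#
# The network wiring is: conv stack (through the last convolutional layer) ->
# flatten -> multi-head self-attention -> position-mean pool -> FC -> softmax.
# Tappable named endpoints:
#   "last_conv"        H' x W' x C activation block of the last conv stage
#   "global_pool"      C-vector: global average pool of the last conv map
#                      (the backbone's own pooled descriptor)
#   "attention_seq"    N x C attention-enhanced sequence SA(X)
#   "attention_pooled" C-vector: mean of SA(X) over positions (feeds the FC)
#   "logits"           n_classes pre-softmax scores
#
# Layers are implemented directly (im2col convolution, 2x2 max pooling) with
# matching backward passes; gradients are checked against finite differences
# in the test-suite. The three named lightweight backbones are reduced conv
# stacks with the canonical last-stage channel counts (they are randomly
# initialised; no pretrained weights are bundled).

# ---- primitive layers -------------------------------------------------------

conv_layer <- function(c_in, c_out, k = 3L, stride = 1L, pad = 1L, seed = 1L) {
  with_seed(seed, {
    fan_in <- k * k * c_in
    W <- matrix(stats::rnorm(fan_in * c_out, 0, sqrt(2 / fan_in)), fan_in, c_out)
    list(type = "conv", W = W, b = numeric(c_out), k = as.integer(k),
         stride = as.integer(stride), pad = as.integer(pad),
         c_in = as.integer(c_in), c_out = as.integer(c_out))
  })
}

pad_map <- function(a, p) {
  if (p == 0) return(a)
  d <- dim(a)
  out <- array(0, dim = c(d[1] + 2 * p, d[2] + 2 * p, d[3]))
  out[(p + 1):(p + d[1]), (p + 1):(p + d[2]), ] <- a
  out
}

# im2col: rows = output positions (column-major over H' x W'), cols = patch
# entries ordered (ki, kj, channel).
im2col <- function(ap, k, stride, h_out, w_out) {
  c_in <- dim(ap)[3]
  M <- matrix(0, h_out * w_out, k * k * c_in)
  for (ki in seq_len(k)) {
    for (kj in seq_len(k)) {
      rows <- seq(ki, by = stride, length.out = h_out)
      cols <- seq(kj, by = stride, length.out = w_out)
      block <- ap[rows, cols, , drop = FALSE]          # h_out x w_out x c_in
      col0 <- ((ki - 1) * k + (kj - 1)) * c_in
      M[, (col0 + 1):(col0 + c_in)] <- matrix(block, h_out * w_out, c_in)
    }
  }
  M
}

conv_forward <- function(layer, a) {
  d <- dim(a)
  stop_if_not(d[3] == layer$c_in,
              sprintf("conv expects %d input channels, got %d", layer$c_in, d[3]))
  k <- layer$k; s <- layer$stride; p <- layer$pad
  h_out <- (d[1] + 2 * p - k) %/% s + 1L
  w_out <- (d[2] + 2 * p - k) %/% s + 1L
  ap <- pad_map(a, p)
  M <- im2col(ap, k, s, h_out, w_out)
  out_flat <- sweep(M %*% layer$W, 2L, layer$b, "+")
  out <- array(out_flat, dim = c(h_out, w_out, layer$c_out))
  list(out = out, cache = list(M = M, dim_in = d, h_out = h_out, w_out = w_out))
}

conv_backward <- function(layer, cache, dout) {
  k <- layer$k; s <- layer$stride; p <- layer$pad
  h_out <- cache$h_out; w_out <- cache$w_out
  dflat <- matrix(dout, h_out * w_out, layer$c_out)
  dW <- t(cache$M) %*% dflat
  db <- colSums(dflat)
  dM <- dflat %*% t(layer$W)
  d <- cache$dim_in
  dap <- array(0, dim = c(d[1] + 2 * p, d[2] + 2 * p, d[3]))
  for (ki in seq_len(k)) {
    for (kj in seq_len(k)) {
      rows <- seq(ki, by = s, length.out = h_out)
      cols <- seq(kj, by = s, length.out = w_out)
      col0 <- ((ki - 1) * k + (kj - 1)) * d[3]
      block <- array(dM[, (col0 + 1):(col0 + d[3])], dim = c(h_out, w_out, d[3]))
      dap[rows, cols, ] <- dap[rows, cols, ] + block
    }
  }
  da <- if (p > 0) dap[(p + 1):(p + d[1]), (p + 1):(p + d[2]), , drop = FALSE] else dap
  list(da = da, dW = dW, db = db)
}

relu_forward <- function(a) list(out = pmax(a, 0), cache = a > 0)
relu_backward <- function(cache, dout) dout * cache

# 2x2 max pool, stride 2; odd trailing rows/columns are cropped.
pool_forward <- function(a) {
  d <- dim(a)
  h2 <- d[1] %/% 2L; w2 <- d[2] %/% 2L
  a <- a[seq_len(2 * h2), seq_len(2 * w2), , drop = FALSE]
  s11 <- a[seq(1, 2 * h2, 2), seq(1, 2 * w2, 2), , drop = FALSE]
  s21 <- a[seq(2, 2 * h2, 2), seq(1, 2 * w2, 2), , drop = FALSE]
  s12 <- a[seq(1, 2 * h2, 2), seq(2, 2 * w2, 2), , drop = FALSE]
  s22 <- a[seq(2, 2 * h2, 2), seq(2, 2 * w2, 2), , drop = FALSE]
  out <- pmax(s11, s21, s12, s22)
  # first-max-wins argmax (1..4) for gradient routing
  arg <- array(1L, dim = dim(out))
  arg[s21 > s11] <- 2L
  m2 <- pmax(s11, s21)
  arg[s12 > m2] <- 3L
  m3 <- pmax(m2, s12)
  arg[s22 > m3] <- 4L
  list(out = out, cache = list(arg = arg, dim_in = d, h2 = h2, w2 = w2))
}

pool_backward <- function(cache, dout) {
  d <- cache$dim_in; h2 <- cache$h2; w2 <- cache$w2
  da <- array(0, dim = d)
  ri <- list(c(1, 1), c(2, 1), c(1, 2), c(2, 2))
  for (m in 1:4) {
    sel <- cache$arg == m
    g <- dout * sel
    rows <- seq(ri[[m]][1], 2 * h2, 2)
    cols <- seq(ri[[m]][2], 2 * w2, 2)
    da[rows, cols, ] <- da[rows, cols, ] + g
  }
  da
}

# ---- model ------------------------------------------------------------------

backbone_stack <- function(backbone, seed) {
  # (c_in, c_out, stride) conv specs; "pool" inserts a 2x2 max pool.
  plan <- switch(backbone,
    toy_cnn = list(c(3, 8, 2), c(8, 16, 2), "pool", c(16, 16, 1)),
    resnet18 = list(c(3, 32, 2), c(32, 64, 2), "pool",
                    c(64, 128, 2), c(128, 512, 1)),
    mobilenet = list(c(3, 32, 2), c(32, 64, 2), "pool",
                     c(64, 128, 2), c(128, 1280, 1)),
    efficientnetb0 = list(c(3, 32, 2), c(32, 64, 2), "pool",
                          c(64, 128, 2), c(128, 1280, 1)),
    stop("unknown backbone: ", backbone)
  )
  layers <- list()
  for (i in seq_along(plan)) {
    sp <- plan[[i]]
    if (identical(sp, "pool")) {
      layers[[length(layers) + 1L]] <- list(type = "pool")
    } else {
      layers[[length(layers) + 1L]] <-
        conv_layer(sp[1], sp[2], stride = sp[3], seed = derive_seed(seed, 101, i))
      layers[[length(layers) + 1L]] <- list(type = "relu")
    }
  }
  layers
}

backbone_channels <- function(backbone) {
  switch(backbone, toy_cnn = 16L, resnet18 = 512L,
         mobilenet = 1280L, efficientnetb0 = 1280L,
         stop("unknown backbone: ", backbone))
}

#' Build an attention-augmented CNN
#'
#' Assembles `backbone-through-last-conv -> flatten -> multi-head attention ->
#' position-mean pool -> FC(n_classes) -> softmax`. The three named
#' lightweight backbones are reduced, randomly initialised conv stacks with
#' the canonical last-stage channel counts (1280 for MobileNet and
#' EfficientNetB0, 512 for ResNet-18); `toy_cnn` is a small 3-block stack
#' (C = 16) meant for tests and desk-scale experiments.
#'
#' @param backbone one of `"efficientnetb0"`, `"mobilenet"`, `"resnet18"`,
#'   `"toy_cnn"`.
#' @param n_classes number of output classes.
#' @param cfg optional [attention_config()]; defaults to 8 heads with the
#'   embedding dimension equal to the backbone's channel count.
#' @param seed integer seed for weight initialisation.
#' @return An object of class `cytodx_model`. Inputs are zero-centred
#'   (`x - 0.5` on `[0, 1]` intensities) before the first convolution.
#' @export
build_attention_model <- function(backbone, n_classes, cfg = NULL, seed = 1L) {
  C <- backbone_channels(backbone)
  if (is.null(cfg)) cfg <- attention_config(C, n_heads = 8L)
  stop_if_not(cfg$channels == C,
              sprintf("attention config channels (%d) must equal backbone C (%d)",
                      cfg$channels, C))
  layers <- backbone_stack(backbone, seed)
  att_w <- attention_weights(cfg, seed = derive_seed(seed, 7))
  fc <- with_seed(derive_seed(seed, 8), {
    list(W = matrix(stats::rnorm(C * n_classes, 0, sqrt(2 / C)), C, n_classes),
         b = numeric(n_classes))
  })
  structure(list(backbone = backbone, layers = layers, att_cfg = cfg,
                 att_w = att_w, fc = fc, n_classes = as.integer(n_classes),
                 channels = C, input_center = 0.5),
            class = "cytodx_model")
}

#' @export
print.cytodx_model <- function(x, ...) {
  cat(sprintf("<cytodx_model> backbone=%s C=%d heads=%d d_k=%d classes=%d\n",
              x$backbone, x$channels, x$att_cfg$n_heads, x$att_cfg$head_dim,
              x$n_classes))
  invisible(x)
}

# Conv stack forward; returns last-conv activation map and per-layer caches.
# Inputs are zero-centred (x - input_center) before the first convolution.
stack_forward <- function(model, img) {
  a <- img - (model$input_center %||% 0)
  caches <- vector("list", length(model$layers))
  for (i in seq_along(model$layers)) {
    ly <- model$layers[[i]]
    r <- switch(ly$type,
      conv = conv_forward(ly, a),
      relu = relu_forward(a),
      pool = pool_forward(a))
    a <- r$out
    caches[[i]] <- r$cache
  }
  list(map = a, caches = caches)
}

# Head forward from the last conv map: attention -> pooled -> logits.
head_forward <- function(model, conv_map) {
  x <- flatten_map(conv_map)
  att <- attention_forward(x, model$att_w, model$att_cfg)
  pooled <- colMeans(att$out)
  logits <- as.numeric(pooled %*% model$fc$W + model$fc$b)
  list(logits = logits, pooled = pooled, att = att,
       seq_dim = c(attr(x, "H"), attr(x, "W")))
}

# Head backward: given d(loss)/d(logits), gradients for FC + attention weights
# and for the conv activation map.
head_backward <- function(model, hf, dlogits) {
  dW_fc <- outer(hf$pooled, dlogits)
  db_fc <- dlogits
  dpooled <- as.numeric(model$fc$W %*% dlogits)
  n_pos <- nrow(hf$att$out)
  dS <- matrix(rep(dpooled / n_pos, each = n_pos), n_pos, length(dpooled))
  ab <- attention_backward(hf$att, dS, model$att_w, model$att_cfg)
  dmap <- unflatten_seq(ab$dx, hf$seq_dim[1], hf$seq_dim[2])
  list(dmap = dmap, dW_fc = dW_fc, db_fc = db_fc,
       dW_Q = ab$dW_Q, dW_K = ab$dW_K, dW_V = ab$dW_V, dW_O = ab$dW_O)
}

stack_backward <- function(model, caches, dmap) {
  da <- dmap
  grads <- vector("list", length(model$layers))
  for (i in rev(seq_along(model$layers))) {
    ly <- model$layers[[i]]
    if (ly$type == "conv") {
      g <- conv_backward(ly, caches[[i]], da)
      da <- g$da
      grads[[i]] <- list(dW = g$dW, db = g$db)
    } else if (ly$type == "relu") {
      da <- relu_backward(caches[[i]], da)
    } else {
      da <- pool_backward(caches[[i]], da)
    }
  }
  grads
}

#' Forward pass with named endpoints
#'
#' @param model a [build_attention_model()] model.
#' @param img an `H x W x 3` numeric array in `[0, 1]`.
#' @return A list with `probs`, plus the endpoint values `last_conv`,
#'   `global_pool`, `attention_seq`, `attention_pooled`, `logits`.
#' @export
forward_model <- function(model, img) {
  sf <- stack_forward(model, img)
  hf <- head_forward(model, sf$map)
  probs <- as.numeric(softmax_rows(matrix(hf$logits, 1)))
  list(probs = probs,
       last_conv = sf$map,
       global_pool = apply(sf$map, 3L, mean),
       attention_seq = hf$att$out,
       attention_pooled = hf$pooled,
       logits = hf$logits)
}

#' Predict class probabilities for a set of images
#'
#' @param model a `cytodx_model`.
#' @param images list of `H x W x 3` arrays.
#' @return An `n x n_classes` matrix of probabilities (rows sum to 1).
#' @export
predict_model <- function(model, images) {
  out <- t(vapply(images, function(im) forward_model(model, im)$probs,
                  numeric(model$n_classes)))
  out
}
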