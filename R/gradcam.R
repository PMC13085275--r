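# Grad-CAM: gradient-weighted class activation mapping. The gradient of the
# target class score (pre-softmax logit) is taken with respect to the chosen
# activation endpoint; channel weights are the spatial means of that
# gradient; the raw map is ReLU of the weighted channel sum, bilinearly
# upsampled to image size and divided by its maximum (an identically-zero
# map stays zero and is flagged).

# Bilinear upsample of an h x w matrix to H x W (align-corners style).
upsample_bilinear <- function(m, H, W) {
  h <- nrow(m); w <- ncol(m)
  ys <- if (h == 1) rep(1, H) else seq(1, h, length.out = H)
  xs <- if (w == 1) rep(1, W) else seq(1, w, length.out = W)
  y0 <- pmin(floor(ys), h - 1L)
  x0 <- pmin(floor(xs), w - 1L)
  if (h == 1) { y0 <- rep(1L, H); fy <- rep(0, H) } else fy <- ys - y0
  if (w == 1) { x0 <- rep(1L, W); fx <- rep(0, W) } else fx <- xs - x0
  y1 <- pmin(y0 + 1L, h); x1 <- pmin(x0 + 1L, w)
  out <- (1 - fy) %o% (1 - fx) * m[cbind(rep(y0, W), rep(x0, each = H))] +
    (1 - fy) %o% fx * m[cbind(rep(y0, W), rep(x1, each = H))] +
    fy %o% (1 - fx) * m[cbind(rep(y1, W), rep(x0, each = H))] +
    fy %o% fx * m[cbind(rep(y1, W), rep(x1, each = H))]
  matrix(out, H, W)
}

# Analytic gradient of logit[target] w.r.t. the last conv activation map
# (and, en route, the attention sequence). Exposed internally so tests can
# compare against finite differences of head_forward().
conv_map_gradient <- function(model, conv_map, target_class) {
  hf <- head_forward(model, conv_map)
  dlogits <- numeric(model$n_classes)
  dlogits[target_class + 1L] <- 1
  hb <- head_backward(model, hf, dlogits)
  n_pos <- nrow(hf$att$out)
  dpooled <- as.numeric(model$fc$W %*% dlogits)
  dS <- matrix(rep(dpooled / n_pos, each = n_pos), n_pos, length(dpooled))
  list(dmap = hb$dmap, dseq = dS, hf = hf)
}

#' Grad-CAM heatmap for one image
#'
#' @param model a [build_attention_model()] model.
#' @param img `H x W x 3` array in `[0, 1]`.
#' @param target_class 0-based class whose evidence is localised; defaults to
#'   the predicted class.
#' @param target_layer `"last_conv"` (default; full spatial resolution before
#'   the attention module) or `"attention_seq"` (the attention-enhanced
#'   sequence reshaped to the map grid).
#' @param alpha overlay blend weight in `[0, 1]`.
#' @return An object of class `heatmap`: `map` (`H x W` in `[0, 1]`, maximum
#'   1 unless the raw map is identically zero, then flagged via
#'   `all_zero = TRUE`), `overlay` (RGB array), `target_class`,
#'   `target_layer`.
#' @export
gradcam <- function(model, img, target_class = NULL,
                    target_layer = c("last_conv", "attention_seq"),
                    alpha = 0.4) {
  target_layer <- match.arg(target_layer)
  sf <- stack_forward(model, img)
  hf <- head_forward(model, sf$map)
  probs <- as.numeric(softmax_rows(matrix(hf$logits, 1)))
  if (is.null(target_class)) target_class <- which.max(probs) - 1L
  stop_if_not(target_class >= 0 && target_class < model$n_classes,
              "target_class out of range")
  g <- conv_map_gradient(model, sf$map, target_class)
  if (target_layer == "last_conv") {
    act <- sf$map
    grad <- g$dmap
  } else {
    act <- unflatten_seq(hf$att$out, dim(sf$map)[1], dim(sf$map)[2])
    grad <- unflatten_seq(g$dseq, dim(sf$map)[1], dim(sf$map)[2])
  }
  weights <- apply(grad, 3L, mean)                     # spatial-mean gradients
  raw <- matrix(0, dim(act)[1], dim(act)[2])
  for (k in seq_len(dim(act)[3])) raw <- raw + weights[k] * act[, , k]
  raw <- pmax(raw, 0)
  H <- dim(img)[1]; W <- dim(img)[2]
  up <- upsample_bilinear(raw, H, W)
  mx <- max(up)
  all_zero <- mx <= 0
  map <- if (all_zero) up * 0 else up / mx
  structure(list(map = map, overlay = overlay_jet(img, map, alpha),
                 target_class = as.integer(target_class),
                 target_layer = target_layer, all_zero = all_zero,
                 channel_weights = weights, probs = probs),
            class = "heatmap")
}

#' Jet colour value for map intensities
#'
#' Piecewise-linear jet: 0 maps to pure blue, 0.5 to green, 1 to pure red,
#' passing through cyan and yellow. Each channel is
#' `clamp(1.5 - |4v - c0|, 0, 1)` with centres `c0 = 3.5` (red), `2` (green),
#' `0.5` (blue).
#'
#' @param v numeric vector/matrix in `[0, 1]`.
#' @return A list of R, G, B components shaped like `v`.
#' @export
jet_rgb <- function(v) {
  ch <- function(c0) pmin(pmax(1.5 - abs(4 * v - c0), 0), 1)
  list(r = ch(3.5), g = ch(2), b = ch(0.5))
}

#' Blend a jet-coloured heatmap over an image
#'
#' Pixelwise `alpha * jet(map) + (1 - alpha) * image`.
#'
#' @param img `H x W x 3` array in `[0, 1]`.
#' @param map `H x W` matrix in `[0, 1]`, same spatial size as `img`.
#' @param alpha blend weight in `[0, 1]`; `alpha = 0` returns the image.
#' @return The blended `H x W x 3` array.
#' @export
overlay_jet <- function(img, map, alpha = 0.4) {
  stop_if_not(all(dim(img)[1:2] == dim(map)), "map and image sizes differ")
  stop_if_not(alpha >= 0 && alpha <= 1, "alpha must be in [0, 1]")
  jet <- jet_rgb(map)
  out <- img
  out[, , 1] <- alpha * jet$r + (1 - alpha) * img[, , 1]
  out[, , 2] <- alpha * jet$g + (1 - alpha) * img[, , 2]
  out[, , 3] <- alpha * jet$b + (1 - alpha) * img[, , 3]
  out
}

#' Batch Grad-CAM with PNG output
#'
#' Writes `<stem>_map.png` (grayscale map) and `<stem>_overlay.png` per image
#' plus a manifest CSV.
#'
#' @param model a model; `images` a list; `dir` output directory.
#' @param target_layer endpoint passed to [gradcam()].
#' @return Invisibly, the manifest data frame.
#' @export
gradcam_batch <- function(model, images, dir, target_layer = "last_conv") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_along(images), function(i) {
    hm <- gradcam(model, images[[i]], target_layer = target_layer)
    mp <- file.path(dir, sprintf("img%03d_map.png", i))
    ov <- file.path(dir, sprintf("img%03d_overlay.png", i))
    png::writePNG(hm$map, mp)
    png::writePNG(hm$overlay, ov)
    data.frame(index = i, map = mp, overlay = ov,
               target_class = hm$target_class, all_zero = hm$all_zero)
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
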