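test_that("heatmaps satisfy the [0, 1] and max-normalisation contract", {
  m <- build_attention_model("toy_cnn", 3, seed = 2)
  img <- array(runif(32 * 32 * 3), dim = c(32, 32, 3))
  hm <- gradcam(m, img, target_class = 1)
  expect_equal(dim(hm$map), c(32, 32))
  expect_gte(min(hm$map), 0)
  expect_lte(max(hm$map), 1)
  if (!hm$all_zero) expect_equal(max(hm$map), 1)
  expect_error(gradcam(m, img, target_class = 3), "target_class")
})

test_that("a channel-0 scorer produces a channel-0 heatmap", {
  # zero Q/K (uniform attention), identity V and O, unit FC weight on
  # channel 0: class score = spatial mean of conv channel 0
  m <- build_attention_model("toy_cnn", 2, seed = 3)
  C <- m$channels
  m$att_w$W_Q <- matrix(0, C, C)
  m$att_w$W_K <- matrix(0, C, C)
  m$att_w$W_V <- diag(C)
  m$att_w$W_O <- diag(C)
  m$fc$W <- matrix(0, C, 2); m$fc$W[1, 1] <- 1
  m$fc$b <- c(0, 0)
  img <- array(runif(32 * 32 * 3), dim = c(32, 32, 3))
  fw <- forward_model(m, img)
  hm <- gradcam(m, img, target_class = 0)
  ref <- pmax(fw$last_conv[, , 1], 0)
  ref_up <- cytodx:::upsample_bilinear(ref, 32, 32)
  expect_gt(max(ref_up), 0)
  expect_equal(hm$map, ref_up / max(ref_up), tolerance = 1e-9)
})

test_that("channel weights match central finite differences", {
  m <- build_attention_model("toy_cnn", 2, seed = 4)
  img <- array(runif(24 * 24 * 3), dim = c(24, 24, 3))
  sf <- cytodx:::stack_forward(m, img)
  target <- 1L
  g <- cytodx:::conv_map_gradient(m, sf$map, target)
  score_of <- function(map) cytodx:::head_forward(m, map)$logits[target + 1]
  n_pos <- prod(dim(sf$map)[1:2])
  eps <- 1e-5
  for (k in c(1, 5, 16)) {
    up <- sf$map; up[, , k] <- up[, , k] + eps
    dn <- sf$map; dn[, , k] <- dn[, , k] - eps
    fd_weight <- (score_of(up) - score_of(dn)) / (2 * eps) / n_pos
    expect_equal(mean(g$dmap[, , k]), fd_weight, tolerance = 1e-6,
                 label = sprintf("channel %d weight", k))
  }
})

test_that("normalised maps are invariant to scoring-head rescaling", {
  m <- build_attention_model("toy_cnn", 2, seed = 5)
  img <- array(runif(32 * 32 * 3), dim = c(32, 32, 3))
  hm1 <- gradcam(m, img, target_class = 0)
  m2 <- m; m2$fc$W <- m$fc$W * 7.5
  hm2 <- gradcam(m2, img, target_class = 0)
  expect_equal(hm1$map, hm2$map, tolerance = 1e-9)
})

test_that("an all-zero gradient is returned as a flagged zero map", {
  m <- build_attention_model("toy_cnn", 2, seed = 6)
  m$fc$W <- matrix(0, m$channels, 2)
  img <- array(runif(32 * 32 * 3), dim = c(32, 32, 3))
  hm <- gradcam(m, img, target_class = 0)
  expect_true(hm$all_zero)
  expect_true(all(hm$map == 0))
})

test_that("the jet overlay blends by the documented piecewise formula", {
  img <- array(0.5, dim = c(4, 4, 3))
  # alpha = 0 is the identity
  expect_equal(overlay_jet(img, matrix(0.7, 4, 4), alpha = 0), img)
  # saturated map at alpha = 1 is pure red
  ov <- overlay_jet(img, matrix(1, 4, 4), alpha = 1)
  expect_equal(ov[, , 1], matrix(1, 4, 4))
  expect_equal(ov[, , 2], matrix(0, 4, 4))
  expect_equal(ov[, , 3], matrix(0, 4, 4))
  # jet endpoints: 0 blue-dominant, 1 red-dominant, 0.5 green-dominant
  j0 <- jet_rgb(0); j1 <- jet_rgb(1); jm <- jet_rgb(0.5)
  expect_true(j0$b > j0$r && j0$b > j0$g)
  expect_true(j1$r > j1$g && j1$r > j1$b)
  expect_true(jm$g >= jm$r && jm$g >= jm$b)
  expect_error(overlay_jet(img, matrix(1, 3, 3)), "sizes differ")
})

test_that("heatmaps focus on the nucleus when it carries the class signal", {
  # classes share cytoplasm morphology entirely; only the nucleus stain
  # differs, so every class's evidence lives at nucleus pixels
  morph <- nucleus_hue_morphology(c(0.1, 0.55), radius = 10, size = 64)
  spec <- fixture_spec(2, c(30, 30), image_size = c(64, 64),
                       class_morphology = morph, seed = 21)
  ds <- make_image_set(spec, with_masks = TRUE)
  m <- build_attention_model("toy_cnn", 2, seed = 13)
  tr <- train_model(m, ds$images, ds$labels,
                    training_config(epochs = 8, learning_rate = 0.01, seed = 4),
                    ranges = identity_ranges())
  pred <- max.col(predict_model(tr$model, ds$images)) - 1L
  expect_gt(mean(pred == ds$labels), 0.9)
  ok <- which(pred == ds$labels)
  ok <- ok[round(seq(1, length(ok), length.out = 24))]
  diffs <- vapply(ok, function(i) {
    hm <- gradcam(tr$model, ds$images[[i]], target_class = ds$labels[i])
    mean(hm$map[ds$masks[[i]]]) - mean(hm$map[!ds$masks[[i]]])
  }, numeric(1))
  expect_gte(length(diffs), 20)
  expect_gt(mean(diffs), 0)                     # nucleus beats cytoplasm
  expect_gt(mean(diffs > 0), 0.8)               # for the vast majority
})

test_that("batch mode writes map/overlay pairs with a manifest", {
  dir <- withr::local_tempdir()
  m <- build_attention_model("toy_cnn", 2, seed = 7)
  imgs <- lapply(1:2, function(i) array(runif(24 * 24 * 3), dim = c(24, 24, 3)))
  manifest <- gradcam_batch(m, imgs, dir)
  expect_equal(nrow(manifest), 2)
  expect_true(all(file.exists(manifest$map)))
  expect_true(all(file.exists(manifest$overlay)))
})
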