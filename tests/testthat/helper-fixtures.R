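# Shared fixture builders for the test-suite. Everything is generated in
# code at test time; no stored data.

# Small labelled image set from a fixture spec (images + labels + masks).
make_image_set <- function(spec, with_masks = FALSE) {
  imgs <- list(); labels <- integer(0); masks <- list()
  for (k in seq_len(spec$n_classes)) {
    for (i in seq_len(spec$per_class_counts[k])) {
      im <- generate_cell_image(k - 1L, spec,
                                seed = derive_seed(spec$seed, k, i),
                                return_mask = with_masks)
      n <- length(imgs) + 1L
      imgs[[n]] <- im
      labels <- c(labels, k - 1L)
      if (with_masks) masks[[n]] <- attr(im, "nucleus_mask")
    }
  }
  list(images = imgs, labels = labels, masks = masks)
}

# Morphology where class identity lives only in the nucleus stain.
nucleus_hue_morphology <- function(hues, radius = 10, size = 64) {
  lapply(hues, function(nh) {
    list(nucleus_radius_mean = radius, nucleus_radius_sd = 0.5,
         nc_ratio = (radius / (size / 2.5))^2, noise_amplitude = 0.02,
         hue = 0.85, nucleus_hue = nh)
  })
}

# Well-separated Gaussian blobs as a feature_matrix. Class k is centred at
# sep * e_k (distinct axes), so classes differ in direction as well as
# location — separable under euclidean AND cosine metrics.
make_blobs <- function(n_per = 20, p = 4, sep = 10, K = 2, seed = 1) {
  stopifnot(K <= p)
  cytodx:::with_seed(seed, {
    X <- do.call(rbind, lapply(seq_len(K), function(k) {
      mu <- numeric(p); mu[k] <- sep
      sweep(matrix(rnorm(n_per * p), n_per, p), 2, mu, "+")
    }))
    feature_matrix(X, rep(seq_len(K) - 1L, each = n_per), source = "synthetic")
  })
}
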