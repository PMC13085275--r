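# Synthetic cytology fixtures: labelled cell-like images and feature matrices
# with a known informative subset, so every downstream stage is testable
# without the external Pap-smear datasets.

#' Specification of a synthetic cytology image dataset
#'
#' Each class is rendered as two concentric filled ellipses (a chromatin-dense
#' "nucleus" inside a paler "cytoplasm") plus Gaussian texture noise and a
#' per-class stain hue shift. This is the minimum structure under which
#' Grad-CAM sanity checks can distinguish nucleus focus from cytoplasm focus.
#'
#' @param n_classes number of classes.
#' @param per_class_counts integer vector (length `n_classes`) of images per
#'   class, all positive.
#' @param image_size `c(height, width)` in pixels, default `c(224, 224)`.
#' @param class_morphology optional list (length `n_classes`) of per-class
#'   parameter lists with elements `nucleus_radius_mean`, `nucleus_radius_sd`
#'   (pixels), `nc_ratio` (nucleus:cytoplasm area ratio in (0,1)),
#'   `noise_amplitude` (chromatin texture noise sd on [0,1] intensities) and
#'   `hue` (stain hue in [0,1]); an optional `nucleus_hue` overrides the
#'   nucleus stain only (useful for fixtures whose class identity must live
#'   inside the nucleus). Defaults spread classes over radius and hue.
#' @param seed integer top-level seed; per-image substreams are derived from it.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_classes, per_class_counts,
                         image_size = c(224L, 224L),
                         class_morphology = NULL,
                         seed = 1L) {
  stop_if_not(length(per_class_counts) == n_classes,
              "per_class_counts must have one entry per class")
  stop_if_not(all(per_class_counts > 0), "per_class_counts must all be > 0")
  stop_if_not(all(image_size >= 8), "image_size must be positive (>= 8 px)")
  if (is.null(class_morphology)) {
    class_morphology <- default_morphology(n_classes, image_size)
  }
  stop_if_not(length(class_morphology) == n_classes,
              "class_morphology must have one entry per class")
  structure(list(
    n_classes = as.integer(n_classes),
    per_class_counts = as.integer(per_class_counts),
    image_size = as.integer(image_size),
    class_morphology = class_morphology,
    seed = as.integer(seed)
  ), class = "fixture_spec")
}

default_morphology <- function(n_classes, image_size) {
  base_r <- min(image_size) / 10
  lapply(seq_len(n_classes), function(k) {
    list(
      nucleus_radius_mean = base_r * (0.6 + 0.5 * (k - 1) / max(1, n_classes - 1)),
      nucleus_radius_sd = base_r * 0.08,
      nc_ratio = 0.12 + 0.05 * (k - 1),
      noise_amplitude = 0.03,
      hue = (k - 1) / n_classes
    )
  })
}

# hue in [0,1] -> RGB triple (full saturation/value); piecewise-linear wheel.
hue_to_rgb <- function(h) {
  h6 <- (h %% 1) * 6
  i <- floor(h6); f <- h6 - i
  switch(as.character(i %% 6),
    "0" = c(1, f, 0), "1" = c(1 - f, 1, 0), "2" = c(0, 1, f),
    "3" = c(0, 1 - f, 1), "4" = c(f, 0, 1), "5" = c(1, 0, 1 - f))
}

#' Render one synthetic cell image
#'
#' Draws a cytoplasm ellipse and a concentric nucleus ellipse whose geometry is
#' sampled from the class morphology parameters, adds Gaussian chromatin
#' texture noise, and clips to `[0, 1]`. Deterministic given the RNG seed.
#'
#' @param class_id zero-based class index in `[0, n_classes)`.
#' @param spec a [fixture_spec()].
#' @param seed integer seed for this image's substream.
#' @param return_mask if `TRUE`, attach nucleus/cytoplasm logical masks as
#'   attributes `"nucleus_mask"` and `"cytoplasm_mask"`.
#' @return An `H x W x 3` numeric array in `[0, 1]` (8-bit-safe RGB).
#' @export
generate_cell_image <- function(class_id, spec, seed = spec$seed,
                                return_mask = FALSE) {
  stop_if_not(class_id >= 0 && class_id < spec$n_classes,
              sprintf("unknown class_id %s (have %d classes)", class_id, spec$n_classes))
  m <- spec$class_morphology[[class_id + 1L]]
  h <- spec$image_size[1]; w <- spec$image_size[2]
  with_seed(seed, {
    r <- m$nucleus_radius_mean +
      if (m$nucleus_radius_sd > 0) stats::rnorm(1, 0, m$nucleus_radius_sd) else 0
    r <- max(1, r)
    ecc <- stats::runif(1, 0.9, 1.1)      # axis ratio; area stays pi * r^2
    ang <- stats::runif(1, 0, pi)
    # cytoplasm radius from the nucleus:cytoplasm area ratio
    rc <- r / sqrt(m$nc_ratio)
    rc <- min(rc, min(h, w) / 2 - 1)
    cx <- w / 2 + stats::runif(1, -w / 12, w / 12)
    cy <- h / 2 + stats::runif(1, -h / 12, h / 12)

    xs <- matrix(rep(seq_len(w), each = h), nrow = h) - cx
    ys <- matrix(rep(seq_len(h), times = w), nrow = h) - cy
    xr <- xs * cos(ang) + ys * sin(ang)
    yr <- -xs * sin(ang) + ys * cos(ang)
    nuc <- (xr / (r * ecc))^2 + (yr / (r / ecc))^2 <= 1
    cyt <- (xs / rc)^2 + (ys / rc)^2 <= 1

    stain <- hue_to_rgb(m$hue)
    nuc_stain <- hue_to_rgb(m$nucleus_hue %||% m$hue)
    bg <- c(0.92, 0.92, 0.94)                       # slide background
    cyto_col <- 0.35 * stain + 0.65 * c(0.85, 0.8, 0.9)
    nuc_col <- 0.75 * nuc_stain * 0.5 + 0.25 * c(0.2, 0.1, 0.35)

    img <- array(0, dim = c(h, w, 3))
    for (ch in 1:3) {
      plane <- matrix(bg[ch], h, w)
      plane[cyt] <- cyto_col[ch]
      plane[nuc] <- nuc_col[ch]
      img[, , ch] <- plane
    }
    if (m$noise_amplitude > 0) {
      img <- img + array(stats::rnorm(h * w * 3, 0, m$noise_amplitude),
                         dim = c(h, w, 3))
    }
    img <- pmin(pmax(img, 0), 1)
    img <- round(img * 255) / 255                    # 8-bit quantisation
    if (return_mask) {
      attr(img, "nucleus_mask") <- nuc
      attr(img, "cytoplasm_mask") <- cyt & !nuc
    }
    img
  })
}

#' Generate an on-disk labelled image dataset
#'
#' Writes one PNG per image into a class-per-subdirectory layout plus a
#' manifest CSV (`path,class_index,class_name,seed`). Labels are dense
#' integers `0..K-1`; the class-name mapping lives only in the manifest.
#'
#' @param spec a [fixture_spec()].
#' @param dir output directory (created if missing).
#' @param class_names optional character vector of class names.
#' @return Invisibly, the manifest `data.frame`.
#' @export
generate_image_dataset <- function(spec, dir, class_names = NULL) {
  if (is.null(class_names)) {
    class_names <- sprintf("class%d", seq_len(spec$n_classes) - 1L)
  }
  ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create output directory: ", dir)
  rows <- vector("list", sum(spec$per_class_counts))
  n <- 0L
  for (k in seq_len(spec$n_classes)) {
    cls_dir <- file.path(dir, class_names[k])
    dir.create(cls_dir, showWarnings = FALSE)
    if (!dir.exists(cls_dir)) stop("unwritable output path: ", cls_dir)
    for (i in seq_len(spec$per_class_counts[k])) {
      s <- derive_seed(spec$seed, k, i)
      img <- generate_cell_image(k - 1L, spec, seed = s)
      p <- file.path(cls_dir, sprintf("img_%04d.png", i))
      png::writePNG(img, p)
      n <- n + 1L
      rows[[n]] <- data.frame(path = p, class_index = k - 1L,
                              class_name = class_names[k], seed = s,
                              stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Load a class-per-subdirectory image dataset
#'
#' Reads every PNG under `dir/<class>/` (or the paths in a manifest if one is
#' present) and returns images plus dense integer labels.
#'
#' @param dir dataset directory as written by [generate_image_dataset()].
#' @return A list with `images` (list of H x W x 3 arrays), `labels`
#'   (0-based integer vector) and `class_names`.
#' @export
load_image_dataset <- function(dir) {
  mf <- file.path(dir, "manifest.csv")
  if (file.exists(mf)) {
    manifest <- utils::read.csv(mf, stringsAsFactors = FALSE)
    imgs <- lapply(manifest$path, png::readPNG)
    return(list(images = imgs, labels = as.integer(manifest$class_index),
                class_names = unique(manifest$class_name)))
  }
  subdirs <- sort(list.dirs(dir, recursive = FALSE))
  stop_if_not(length(subdirs) > 0, "no class sub-directories found")
  imgs <- list(); labels <- integer(0)
  for (k in seq_along(subdirs)) {
    files <- sort(list.files(subdirs[k], pattern = "\\.png$", full.names = TRUE))
    imgs <- c(imgs, lapply(files, png::readPNG))
    labels <- c(labels, rep(k - 1L, length(files)))
  }
  list(images = imgs, labels = labels, class_names = basename(subdirs))
}

#' Specification of a synthetic deep-feature matrix
#'
#' Stands in for extracted deep features: `k_informative` columns carry
#' class-dependent means (adjacent class means separated by
#' `effect_size * noise_sd`), the rest are exchangeable Gaussian noise.
#'
#' @param n_samples,p_features,k_informative,n_classes integers;
#'   `k_informative <= p_features`, `n_samples >= n_classes`.
#' @param effect_size standardised between-class mean shift.
#' @param noise_sd within-class standard deviation.
#' @param seed integer seed.
#' @return An object of class `synthetic_feature_spec`.
#' @export
synthetic_feature_spec <- function(n_samples, p_features, k_informative,
                                   effect_size = 1, noise_sd = 1,
                                   n_classes = 2L, seed = 1L) {
  stop_if_not(k_informative <= p_features, "k_informative > p_features")
  stop_if_not(n_samples >= n_classes, "need n_samples >= n_classes")
  structure(list(n_samples = as.integer(n_samples),
                 p_features = as.integer(p_features),
                 k_informative = as.integer(k_informative),
                 effect_size = effect_size, noise_sd = noise_sd,
                 n_classes = as.integer(n_classes), seed = as.integer(seed)),
            class = "synthetic_feature_spec")
}

#' Generate a synthetic feature matrix with planted informative columns
#'
#' @param spec a [synthetic_feature_spec()].
#' @return A list with `features` (a [feature_matrix()]), `labels` and
#'   `informative_indices` (1-based column indices of the planted columns).
#' @export
generate_feature_matrix <- function(spec) {
  with_seed(spec$seed, {
    n <- spec$n_samples; p <- spec$p_features; K <- spec$n_classes
    labels <- rep(seq_len(K) - 1L, length.out = n)
    labels <- sample(labels)
    X <- matrix(stats::rnorm(n * p, 0, spec$noise_sd), n, p)
    info <- sort(sample.int(p, spec$k_informative))
    sep <- spec$effect_size * spec$noise_sd
    levels <- (seq_len(K) - (K + 1) / 2) * sep
    for (j in info) {
      perm <- sample.int(K)                 # class-to-level assignment varies
      X[, j] <- X[, j] + levels[perm][labels + 1L]
    }
    fm <- feature_matrix(X, labels, source = "synthetic", network = "synthetic",
                         feature_names = sprintf("f%d", seq_len(p) - 1L))
    list(features = fm, labels = labels, informative_indices = info)
  })
}
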