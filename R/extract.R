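# Dual deep-layer feature extraction: one row per image from each of the two
# tapped endpoints of a trained attention model. Both layers yield length-C
# vectors (C = backbone channel count).

resize_if_needed <- function(img, model) {
  # Models are size-agnostic (global pooling head), but a degenerate map
  # (fewer than 2x2 spatial positions) is rejected early.
  stop_if_not(length(dim(img)) == 3 && dim(img)[3] == 3,
              "expected an H x W x 3 RGB image")
  img
}

extract_matrix <- function(model, images, endpoint) {
  stop_if_not(length(images) > 0, "no images supplied")
  vals <- t(vapply(images, function(im) {
    im <- resize_if_needed(im, model)
    forward_model(model, im)[[endpoint]]
  }, numeric(model$channels)))
  vals
}

#' Extract pooling-layer deep features
#'
#' Taps the backbone's last pooling descriptor (global average pool of the
#' last convolutional map): a compact summary of global morphology. One row
#' per image, `p = C` of the backbone; deterministic in evaluation mode.
#'
#' @param model a trained (or initialised) [build_attention_model()] model.
#' @param images list of `H x W x 3` arrays.
#' @param labels 0-based integer labels aligned with `images`.
#' @return A [feature_matrix()] with `source = "pooling"`.
#' @export
extract_pooling_features <- function(model, images, labels) {
  vals <- extract_matrix(model, images, "global_pool")
  feature_matrix(vals, labels, source = "pooling", network = model$backbone)
}

#' Extract self-attention-layer deep features
#'
#' Taps the attention-enhanced sequence `SA(X)` and mean-pools it over the
#' `N` positions into one length-`C` vector per image: the contextual,
#' attention-weighted counterpart of the pooling descriptor.
#'
#' @inheritParams extract_pooling_features
#' @return A [feature_matrix()] with `source = "attention"`.
#' @export
extract_attention_features <- function(model, images, labels) {
  vals <- extract_matrix(model, images, "attention_pooled")
  feature_matrix(vals, labels, source = "attention", network = model$backbone)
}
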