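# FeatureMatrix: the currency of the downstream pipeline. An n x p numeric
# matrix of deep features with aligned 0-based integer class labels plus
# provenance (which layer and which backbone it came from).

#' Construct a feature matrix
#'
#' @param values numeric `n x p` matrix, no non-finite entries.
#' @param labels length-`n` integer vector of 0-based class labels.
#' @param source one of `"pooling"`, `"attention"`, `"concat"`, `"fused"`,
#'   `"ensemble"`, or `"synthetic"`.
#' @param network backbone name the features came from.
#' @param feature_names length-`p` identifiers (default `f0..f{p-1}`).
#' @param allow_empty permit `p = 0` (edge case used by concatenation
#'   identities); normal matrices require `p > 0`.
#' @return An object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, labels,
                           source = c("pooling", "attention", "concat",
                                      "fused", "ensemble", "synthetic"),
                           network = "unknown", feature_names = NULL,
                           allow_empty = FALSE) {
  source <- match.arg(source)
  values <- as.matrix(values)
  stop_if_not(nrow(values) == length(labels),
              "labels length must equal number of rows")
  stop_if_not(allow_empty || ncol(values) > 0,
              "feature matrix needs p > 0 columns")
  stop_if_not(all(is.finite(values)), "feature matrix has non-finite entries")
  if (is.null(feature_names)) {
    feature_names <- sprintf("f%d", seq_len(ncol(values)) - 1L)
  }
  stop_if_not(length(feature_names) == ncol(values),
              "feature_names length must equal number of columns")
  colnames(values) <- feature_names
  structure(list(values = values, labels = as.integer(labels),
                 source = source, network = network,
                 feature_names = feature_names),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d samples x %d features [%s / %s], %d classes\n",
              nrow(x$values), ncol(x$values), x$source, x$network,
              length(unique(x$labels))))
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

#' Write / read a feature matrix as CSV (+ sidecar JSON metadata)
#'
#' The CSV header carries the feature names with a final `label` column; the
#' sidecar `<path>.meta.json` records `source` and `network` so the round-trip
#' is lossless.
#'
#' @param fm a [feature_matrix()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_csv <- function(fm, path) {
  df <- as.data.frame(fm$values)
  names(df) <- fm$feature_names
  df$label <- fm$labels
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(list(source = fm$source, network = fm$network),
                       paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  stop_if_not("label" %in% names(df), "CSV lacks a 'label' column")
  meta <- list(source = "synthetic", network = "unknown")
  mp <- paste0(path, ".meta.json")
  if (file.exists(mp)) meta <- jsonlite::read_json(mp, simplifyVector = TRUE)
  lab <- as.integer(df$label)
  vals <- as.matrix(df[setdiff(names(df), "label")])
  feature_matrix(vals, lab, source = meta$source, network = meta$network,
                 feature_names = setdiff(names(df), "label"))
}

#' Write / read a feature matrix as a binary container (RDS)
#'
#' Binary equivalent of the CSV format; round-trips losslessly at full double
#' precision and keeps the provenance fields inline.
#'
#' @param fm a [feature_matrix()].
#' @param path output `.rds` path.
#' @export
write_feature_bin <- function(fm, path) {
  saveRDS(unclass(fm), path)
  invisible(path)
}

#' @rdname write_feature_bin
#' @export
read_feature_bin <- function(path) {
  x <- readRDS(path)
  feature_matrix(x$values, x$labels, source = x$source, network = x$network,
                 feature_names = x$feature_names)
}

#' Concatenate pooling-layer and attention-layer features of one backbone
#'
#' Column-binds the two dual-layer feature sets of the same network (pooling
#' columns first), giving the `2C`-length representation that feeds the
#' wavelet fusion step.
#'
#' @param pool_f,attn_f [feature_matrix()] objects with identical labels and
#'   network.
#' @return A `feature_matrix` with `source = "concat"`; column provenance is
#'   kept in `feature_names` (`pool_*` then `attn_*`).
#' @export
concat_dual <- function(pool_f, attn_f) {
  stop_if_not(identical(pool_f$labels, attn_f$labels),
              "label vectors differ between the two layers")
  stop_if_not(identical(pool_f$network, attn_f$network),
              "feature sets come from different networks")
  vals <- cbind(pool_f$values, attn_f$values)
  nm <- c(paste0("pool_", pool_f$feature_names, recycle0 = TRUE),
          paste0("attn_", attn_f$feature_names, recycle0 = TRUE))
  feature_matrix(vals, pool_f$labels, source = "concat",
                 network = pool_f$network, feature_names = nm)
}
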