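# Haar discrete wavelet transform fusion of dual-layer deep features.
#
# The concatenated (pooling + attention) feature vector of each image is run
# through a 1-D orthonormal Haar analysis step once or twice; only the
# approximation coefficients (CA) of the final level are retained. With the
# 1/sqrt(2) filter convention the step is orthonormal, so
# ||CA||^2 + ||CD||^2 = ||v||^2 (Parseval), which the tests exploit.

#' One orthonormal Haar analysis step
#'
#' Pairs consecutive samples: `CA_i = (v_{2i-1} + v_{2i}) / sqrt(2)`,
#' `CD_i = (v_{2i-1} - v_{2i}) / sqrt(2)`. Odd-length inputs are
#' symmetric-padded with one trailing reflected sample (never triggered by
#' the in-scope lengths, which are divisible by 4).
#'
#' @param v numeric vector, length >= 2.
#' @return A list with `CA` (approximation) and `CD` (detail) coefficients.
#' @export
haar_step <- function(v) {
  m <- length(v)
  stop_if_not(m >= 2, "haar_step needs length >= 2")
  if (m %% 2 == 1) v <- c(v, v[m])      # symmetric boundary extension
  even <- v[seq(2, length(v), 2)]
  odd <- v[seq(1, length(v), 2)]
  list(CA = (odd + even) / sqrt(2), CD = (odd - even) / sqrt(2))
}

#' Fused feature set (concatenation + Haar DWT, CA only)
#'
#' Applies [haar_step()] recursively `level` times to every row of a
#' concatenated dual-layer matrix, each time keeping the running CA (detail
#' coefficients are computed and discarded). Output lengths per backbone:
#' level 1 halves `2C`, level 2 quarters it (512/256 for ResNet-18,
#' 1280/640 for MobileNet and EfficientNetB0).
#'
#' @param concat_f a [concat_dual()] feature matrix (`p = 2C`).
#' @param level decomposition level, 1 or 2.
#' @return An object of class `fused_feature_set`: a list with `matrix` (a
#'   `feature_matrix` with `source = "fused"`), `level`, `wavelet = "haar"`,
#'   `parent_network`.
#' @export
dwt_fuse <- function(concat_f, level) {
  stop_if_not(level %in% c(1L, 2L), "level must be 1 or 2")
  vals <- concat_f$values
  for (l in seq_len(level)) {
    p <- ncol(vals)
    if (p %% 2 == 1) vals <- cbind(vals, vals[, p, drop = FALSE])
    odd <- seq(1, ncol(vals), 2); even <- seq(2, ncol(vals), 2)
    vals <- (vals[, odd, drop = FALSE] + vals[, even, drop = FALSE]) / sqrt(2)
  }
  nm <- sprintf("%s_dwt%d_ca%d", concat_f$network, level, seq_len(ncol(vals)) - 1L)
  fm <- feature_matrix(vals, concat_f$labels, source = "fused",
                       network = concat_f$network, feature_names = nm)
  structure(list(matrix = fm, level = as.integer(level), wavelet = "haar",
                 parent_network = concat_f$network),
            class = "fused_feature_set")
}

#' @export
print.fused_feature_set <- function(x, ...) {
  cat(sprintf("<fused_feature_set> %s haar level-%d: %d x %d\n",
              x$parent_network, x$level, nrow(x$matrix$values),
              ncol(x$matrix$values)))
  invisible(x)
}

#' Write a fused feature set (CSV + sidecar with level/wavelet)
#' @param fs a [dwt_fuse()] result.
#' @param path output CSV path.
#' @export
write_fused_csv <- function(fs, path) {
  write_feature_csv(fs$matrix, path)
  jsonlite::write_json(list(source = "fused", network = fs$parent_network,
                            level = fs$level, wavelet = fs$wavelet),
                       paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(path)
}
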