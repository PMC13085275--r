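# Cross-network ensembling and one-way ANOVA F-ratio feature selection.
#
# Each feature's discriminative power is the ratio of between-class to
# within-class mean squares, F = MSB / MSW with df (K-1, n-K). Features are
# ranked by descending F; selection is the top-k prefix. Degenerate cases:
# zero within-class variance with unequal class means gives F = +Inf (ranked
# first); a globally constant column gives F = 0 (ranked last). Ties break on
# the lower column index, so selection is deterministic.

#' Concatenate fused feature sets across networks
#'
#' Column-binds the per-network fused sets in the fixed order efficientnetb0,
#' mobilenet, resnet18 (unknown networks keep their given order, after the
#' known ones); provenance is kept in the feature names.
#'
#' @param sets list of [dwt_fuse()] results (or `feature_matrix` objects)
#'   sharing identical labels.
#' @return A [feature_matrix()] with `source = "ensemble"`.
#' @export
concat_networks <- function(sets) {
  stop_if_not(length(sets) >= 1, "need at least one feature set")
  mats <- lapply(sets, function(s) if (inherits(s, "fused_feature_set")) s$matrix else s)
  labs <- mats[[1]]$labels
  for (m in mats) {
    stop_if_not(identical(m$labels, labs), "label vectors differ across sets")
  }
  order_key <- match(vapply(mats, function(m) m$network, character(1)),
                     c("efficientnetb0", "mobilenet", "resnet18"))
  order_key[is.na(order_key)] <- 4L
  mats <- mats[order(order_key)]
  vals <- do.call(cbind, lapply(mats, function(m) m$values))
  nm <- unlist(lapply(mats, function(m) paste(m$network, m$feature_names, sep = ".")))
  feature_matrix(vals, labs, source = "ensemble", network = "ensemble",
                 feature_names = nm)
}

#' Per-feature one-way ANOVA F-ratios
#'
#' Vectorised over columns: per feature, `F = MSB / MSW` with
#' `MSB = SSB / (K-1)`, `MSW = SSW / (n-K)`; p-values from the F
#' distribution. Requires at least two classes and at least two samples per
#' class.
#'
#' @param x a [feature_matrix()].
#' @return An object of class `feature_ranking`: `f_scores`, `p_values`,
#'   `order` (1-based permutation sorting F descending, ties to the lower
#'   index), `df` and the tie policy.
#' @export
anova_f_scores <- function(x) {
  vals <- x$values
  labs <- x$labels
  counts <- table(labs)
  stop_if_not(length(counts) >= 2, "need >= 2 classes")
  stop_if_not(all(counts >= 2),
              paste("class(es) with a single sample:",
                    paste(names(counts)[counts < 2], collapse = ", ")))
  n <- nrow(vals); K <- length(counts)
  grand <- colMeans(vals)
  ssb <- numeric(ncol(vals))
  ssw <- numeric(ncol(vals))
  for (g in names(counts)) {
    rows <- labs == as.integer(g)
    gm <- colMeans(vals[rows, , drop = FALSE])
    ssb <- ssb + sum(rows) * (gm - grand)^2
    ssw <- ssw + colSums(sweep(vals[rows, , drop = FALSE], 2L, gm)^2)
  }
  msb <- ssb / (K - 1)
  msw <- ssw / (n - K)
  f <- ifelse(msw > 0, msb / msw,
              ifelse(msb > 0, Inf, 0))        # degenerate-separation policy
  p <- ifelse(is.finite(f), stats::pf(f, K - 1, n - K, lower.tail = FALSE),
              0)
  p[f == 0 & msw == 0] <- NA_real_            # globally constant: p undefined
  f <- unname(f); p <- unname(p)
  ord <- order(-f, seq_along(f))              # ties -> lower column index
  structure(list(f_scores = f, p_values = p, order = ord,
                 df = c(K - 1L, n - K), tie_policy = "lower column index",
                 feature_names = x$feature_names),
            class = "feature_ranking")
}

#' @export
print.feature_ranking <- function(x, ...) {
  cat(sprintf("<feature_ranking> %d features, df = (%d, %d); top: %s\n",
              length(x$f_scores), x$df[1], x$df[2],
              paste(utils::head(x$feature_names[x$order], 3), collapse = ", ")))
  invisible(x)
}

#' Select the top-k ranked features
#'
#' @param ranking a [anova_f_scores()] ranking.
#' @param k number of features to keep, `1 <= k <= p`.
#' @return Sorted 1-based column indices of the selected features.
#' @export
select_top_k <- function(ranking, k) {
  p <- length(ranking$f_scores)
  stop_if_not(k >= 1 && k <= p, sprintf("k must be in [1, %d]", p))
  sort(ranking$order[seq_len(k)])
}

#' Export a feature ranking as CSV
#'
#' Columns: `feature_name, network, F, p, rank`.
#'
#' @param ranking a [anova_f_scores()] ranking.
#' @param path output CSV path.
#' @export
write_ranking_csv <- function(ranking, path) {
  nm <- ranking$feature_names
  network <- sub("\\..*$", "", nm)
  network[!grepl("\\.", nm)] <- NA
  rank <- integer(length(nm)); rank[ranking$order] <- seq_along(nm)
  utils::write.csv(data.frame(feature_name = nm, network = network,
                              F = ranking$f_scores, p = ranking$p_values,
                              rank = rank),
                   path, row.names = FALSE)
  invisible(path)
}

#' Top-k sweep across classifiers
#'
#' For each grid value `k`, evaluates every classifier on the top-k ANOVA
#' features under repeated stratified cross-validation and records the mean
#' accuracy. Mirrors the feature-count sweep used to pick the operating
#' point of the ensemble.
#'
#' @param x a [feature_matrix()] (normally the ensemble concatenation).
#' @param classifiers character vector of classifier names (see
#'   [classifier_spec()]).
#' @param grid integer vector of k values (clipped at p).
#' @param n_folds,n_repeats,seed cross-validation controls.
#' @return A list with `accuracy` (classifier x k matrix), `best_k` (named
#'   vector, argmax k per classifier) and the `ranking`.
#' @export
sweep_k <- function(x, classifiers = classifier_names(),
                    grid = seq(100, 1500, by = 100),
                    n_folds = 5L, n_repeats = 1L, seed = 1L) {
  p <- ncol(x$values)
  grid <- unique(pmin(as.integer(grid), p))
  stop_if_not(all(grid >= 1), "grid values must be >= 1")
  ranking <- anova_f_scores(x)
  acc <- matrix(NA_real_, length(classifiers), length(grid),
                dimnames = list(classifiers, as.character(grid)))
  for (j in seq_along(grid)) {
    idx <- select_top_k(ranking, grid[j])
    sub <- feature_matrix(x$values[, idx, drop = FALSE], x$labels,
                          source = x$source, network = x$network,
                          feature_names = x$feature_names[idx])
    rep <- cv_evaluate(sub, classifiers = classifiers, n_folds = n_folds,
                       n_repeats = n_repeats, seed = seed)
    acc[, j] <- vapply(classifiers,
                       function(cl) rep$metrics[[cl]]$mean[["Accuracy"]],
                       numeric(1))
  }
  best <- grid[apply(acc, 1L, which.max)]
  names(best) <- classifiers
  list(accuracy = acc, best_k = best, ranking = ranking, grid = grid)
}
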