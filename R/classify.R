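# Seven-classifier evaluation harness: four SVM kernels (linear, quadratic,
# cubic, Gaussian), two KNNs (euclidean and cosine metric, k = 10) and LDA,
# under repeated stratified 5-fold cross-validation. Metrics follow the
# one-vs-rest binarisation: per class, Sensitivity = TP/(TP+FN),
# Specificity = TN/(TN+FP), Precision = TP/(TP+FP), F1 = 2TP/(2TP+FP+FN),
# MCC = (TP*TN - FP*FN)/sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)); macro values are
# unweighted means over classes; overall Accuracy is trace/total.

#' The seven evaluated classifiers
#' @return Character vector of classifier names.
#' @export
classifier_names <- function() {
  c("LSVM", "QSVM", "CSVM", "GSVM", "MKNN", "CKNN", "LDA")
}

#' Classifier specification
#'
#' @param name one of `LSVM`, `QSVM`, `CSVM`, `GSVM` (SVM with linear,
#'   quadratic, cubic, Gaussian kernel; one-vs-one multiclass voting, box
#'   constraint 1, kernel scale `sqrt(p)` i.e. `gamma = 1/p`), `MKNN`
#'   (euclidean KNN, k = 10), `CKNN` (cosine KNN, k = 10), `LDA` (linear
#'   discriminant; ridge-regularised when the pooled covariance is singular).
#' @param k_neighbors neighbour count for the KNN variants.
#' @param standardize standardise features using train-fold statistics
#'   (applied to all but the cosine KNN, whose metric is scale-free per row).
#' @return An object of class `classifier_spec`.
#' @export
classifier_spec <- function(name, k_neighbors = 10L, standardize = TRUE) {
  name <- match.arg(name, classifier_names())
  structure(list(name = name, k_neighbors = as.integer(k_neighbors),
                 standardize = isTRUE(standardize) && name != "CKNN"),
            class = "classifier_spec")
}

# Train-fold standardisation; constant columns keep sd 1.
fit_scaler <- function(x) {
  mu <- colMeans(x)
  sd <- apply(x, 2L, stats::sd)
  sd[!is.finite(sd) | sd == 0] <- 1
  list(mu = mu, sd = sd)
}
apply_scaler <- function(x, sc) sweep(sweep(x, 2L, sc$mu), 2L, sc$sd, "/")

svm_kernel_args <- function(name, p) {
  # MATLAB-style kernel scale sqrt(p) corresponds to gamma = 1/p here.
  switch(name,
    LSVM = list(kernel = "linear"),
    QSVM = list(kernel = "polynomial", degree = 2L, gamma = 1 / p, coef0 = 1),
    CSVM = list(kernel = "polynomial", degree = 3L, gamma = 1 / p, coef0 = 1),
    GSVM = list(kernel = "radial", gamma = 1 / p))
}

# Aggregate one-vs-one decision values into per-class margin scores.
ovo_scores <- function(dec, classes) {
  K <- length(classes)
  sc <- matrix(0, nrow(dec), K, dimnames = list(NULL, classes))
  pairs <- strsplit(colnames(dec), "/")
  for (j in seq_along(pairs)) {
    a <- pairs[[j]][1]; b <- pairs[[j]][2]
    sc[, a] <- sc[, a] + dec[, j]
    sc[, b] <- sc[, b] - dec[, j]
  }
  sc
}

knn_predict <- function(train_x, train_y, test_x, k, metric) {
  k <- min(k, nrow(train_x))
  if (metric == "cosine") {
    norm_rows <- function(m) {
      n <- sqrt(rowSums(m^2)); n[n == 0] <- 1
      m / n
    }
    d <- 1 - norm_rows(test_x) %*% t(norm_rows(train_x))
  } else {
    d <- outer(rowSums(test_x^2), rowSums(train_x^2), "+") -
      2 * test_x %*% t(train_x)
  }
  classes <- sort(unique(train_y))
  K <- length(classes)
  scores <- matrix(0, nrow(test_x), K, dimnames = list(NULL, classes))
  pred <- integer(nrow(test_x))
  for (i in seq_len(nrow(test_x))) {
    nb <- order(d[i, ], seq_len(ncol(d)))[seq_len(k)]  # distance, then index
    votes <- table(factor(train_y[nb], levels = classes))
    scores[i, ] <- as.numeric(votes) / k
    pred[i] <- classes[which.max(votes)]               # vote tie: lower class
  }
  list(pred = pred, scores = scores)
}

# Regularised LDA fallback: pooled covariance + ridge, softmax posteriors.
ridge_lda <- function(train_x, train_y, test_x) {
  classes <- sort(unique(train_y))
  p <- ncol(train_x); n <- nrow(train_x)
  mus <- t(vapply(classes, function(g) colMeans(train_x[train_y == g, , drop = FALSE]),
                  numeric(p)))
  S <- matrix(0, p, p)
  for (gi in seq_along(classes)) {
    xc <- sweep(train_x[train_y == classes[gi], , drop = FALSE], 2L, mus[gi, ])
    S <- S + crossprod(xc)
  }
  S <- S / max(1, n - length(classes))
  S <- S + diag(mean(diag(S)) * 1e-6 + 1e-10, p)
  Sinv <- solve(S)
  priors <- as.numeric(table(factor(train_y, levels = classes))) / n
  disc <- vapply(seq_along(classes), function(gi) {
    w <- Sinv %*% mus[gi, ]
    as.numeric(test_x %*% w) - 0.5 * sum(mus[gi, ] * w) + log(priors[gi])
  }, numeric(nrow(test_x)))
  disc <- matrix(disc, nrow(test_x), length(classes),
                 dimnames = list(NULL, classes))
  post <- softmax_rows(disc)
  list(pred = classes[max.col(post, ties.method = "first")], scores = post)
}

#' Fit a classifier on a train fold and predict a test fold
#'
#' Standardisation statistics are fit on the train fold only and applied to
#' both folds. SVMs use one-vs-one voting; their per-class scores are
#' aggregated pairwise decision margins. KNNs score by neighbour-vote
#' fractions; LDA by posterior probabilities.
#'
#' @param spec a [classifier_spec()] (or a classifier name).
#' @param train,test [feature_matrix()] objects with identical columns.
#' @return A list with `pred` (0-based integer predictions) and `scores`
#'   (`n_test x K` matrix, columns named by class).
#' @export
fit_predict <- function(spec, train, test) {
  if (is.character(spec)) spec <- classifier_spec(spec)
  stop_if_not(identical(train$feature_names, test$feature_names),
              "train/test feature columns differ")
  trx <- train$values; tex <- test$values
  if (spec$standardize) {
    sc <- fit_scaler(trx)
    trx <- apply_scaler(trx, sc)
    tex <- apply_scaler(tex, sc)
  }
  y <- train$labels
  classes <- sort(unique(y))
  if (spec$name %in% c("LSVM", "QSVM", "CSVM", "GSVM")) {
    ka <- svm_kernel_args(spec$name, ncol(trx))
    fit <- do.call(e1071::svm,
                   c(list(x = trx, y = factor(y, levels = classes),
                          scale = FALSE, cost = 1), ka))
    pr <- stats::predict(fit, tex, decision.values = TRUE)
    dec <- attr(pr, "decision.values")
    scores <- ovo_scores(dec, as.character(classes))
    list(pred = as.integer(as.character(pr)), scores = scores)
  } else if (spec$name == "MKNN") {
    knn_predict(trx, y, tex, spec$k_neighbors, "euclidean")
  } else if (spec$name == "CKNN") {
    knn_predict(trx, y, tex, spec$k_neighbors, "cosine")
  } else {
    res <- tryCatch({
      fit <- withCallingHandlers(
        MASS::lda(trx, grouping = factor(y, levels = classes)),
        warning = function(w) {
          if (grepl("collinear", conditionMessage(w))) {
            invokeRestart("muffleWarning")
          }
        })
      pr <- stats::predict(fit, tex)
      list(pred = as.integer(as.character(pr$class)),
           scores = pr$posterior)
    }, error = function(e) NULL)
    if (is.null(res)) {
      message("LDA: singular within-class covariance; ridge regularisation applied")
      res <- ridge_lda(trx, y, tex)
      res$pred <- as.integer(res$pred)
    }
    res
  }
}

#' Stratified cross-validation folds
#'
#' Within each repeat the folds partition the sample indices; each fold's
#' class proportions match the global proportions to within one sample per
#' class (round-robin dealing of a shuffled class).
#'
#' @param labels 0-based integer labels.
#' @param n_folds folds per repeat (every class needs >= `n_folds` members).
#' @param n_repeats independent repeats.
#' @param seed integer seed.
#' @return A list of repeats, each a list of `n_folds` index vectors.
#' @export
stratified_folds <- function(labels, n_folds = 5L, n_repeats = 1L, seed = 1L) {
  counts <- table(labels)
  too_small <- names(counts)[counts < n_folds]
  stop_if_not(length(too_small) == 0,
              paste("class(es) smaller than n_folds:",
                    paste(too_small, collapse = ", ")))
  with_seed(seed, {
    lapply(seq_len(n_repeats), function(r) {
      folds <- vector("list", n_folds)
      for (g in names(counts)) {
        idx <- sample(which(labels == as.integer(g)))
        assign_to <- rep(seq_len(n_folds), length.out = length(idx))
        for (f in seq_len(n_folds)) {
          folds[[f]] <- c(folds[[f]], idx[assign_to == f])
        }
      }
      lapply(folds, sort)
    })
  })
}

#' Confusion matrix
#'
#' @param y_true,y_pred 0-based integer labels in `[0, K)`.
#' @param K number of classes.
#' @return `K x K` integer matrix, rows = true class, columns = predicted.
#' @export
confusion <- function(y_true, y_pred, K) {
  stop_if_not(all(y_true >= 0 & y_true < K) && all(y_pred >= 0 & y_pred < K),
              "labels out of range [0, K)")
  cm <- table(factor(y_true, levels = 0:(K - 1)),
              factor(y_pred, levels = 0:(K - 1)))
  m <- matrix(as.integer(cm), K, K,
              dimnames = list(true = 0:(K - 1), pred = 0:(K - 1)))
  m
}

binary_counts <- function(cm, c) {
  tp <- cm[c, c]
  fn <- sum(cm[c, ]) - tp
  fp <- sum(cm[, c]) - tp
  tn <- sum(cm) - tp - fn - fp
  c(TP = tp, TN = tn, FP = fp, FN = fn)
}

safe_div <- function(num, den) if (den == 0) 0 else num / den

#' Classification metrics from a confusion matrix
#'
#' Per class, the matrix is binarised one-vs-rest and Sensitivity,
#' Specificity, Precision, F1, MCC and binary Accuracy are computed; macro
#' values are unweighted means over classes, and the overall Accuracy is
#' `trace / total`. Zero-denominator metrics are defined as 0 and flagged.
#'
#' @param cm a [confusion()] matrix.
#' @return A list with `per_class` (data frame), `macro` (named vector:
#'   Accuracy, Precision, F1, Specificity, MCC, Sensitivity) and a
#'   `zero_denominator` flag.
#' @export
metrics_from_confusion <- function(cm) {
  K <- nrow(cm)
  stop_if_not(sum(cm) > 0, "empty confusion matrix")
  flagged <- FALSE
  rows <- lapply(seq_len(K), function(c) {
    b <- binary_counts(cm, c)
    dens <- c(b["TP"] + b["FN"], b["TN"] + b["FP"], b["TP"] + b["FP"],
              2 * b["TP"] + b["FP"] + b["FN"])
    if (any(dens == 0)) flagged <<- TRUE
    mcc_den <- sqrt(prod(c(b["TP"] + b["FP"], b["TP"] + b["FN"],
                           b["TN"] + b["FP"], b["TN"] + b["FN"])))
    data.frame(
      class = c - 1L,
      Sensitivity = safe_div(b[["TP"]], b[["TP"]] + b[["FN"]]),
      Specificity = safe_div(b[["TN"]], b[["TN"]] + b[["FP"]]),
      Precision = safe_div(b[["TP"]], b[["TP"]] + b[["FP"]]),
      MCC = if (mcc_den == 0) { flagged <<- TRUE; 0 } else
        (b[["TP"]] * b[["TN"]] - b[["FP"]] * b[["FN"]]) / mcc_den,
      F1 = safe_div(2 * b[["TP"]], 2 * b[["TP"]] + b[["FP"]] + b[["FN"]]),
      Accuracy = (b[["TP"]] + b[["TN"]]) / sum(b))
  })
  per_class <- do.call(rbind, rows)
  macro <- c(Accuracy = sum(diag(cm)) / sum(cm),
             Precision = mean(per_class$Precision),
             F1 = mean(per_class$F1),
             Specificity = mean(per_class$Specificity),
             MCC = mean(per_class$MCC),
             Sensitivity = mean(per_class$Sensitivity))
  list(per_class = per_class, macro = macro, zero_denominator = flagged)
}

#' One-vs-rest ROC curves and AUC
#'
#' For each class the score column is swept over thresholds; AUC by the
#' trapezoid rule. A class absent from `y_true` gets `NA` AUC and is
#' flagged.
#'
#' @param scores `n x K` score matrix (higher = more class-like), columns in
#'   class order `0..K-1`.
#' @param y_true 0-based integer labels.
#' @return A list with `roc` (per-class data frames of FPR/TPR points),
#'   `auc` (length-K vector) and `undefined` (classes with no positives or
#'   no negatives).
#' @export
roc_ovr <- function(scores, y_true) {
  K <- ncol(scores)
  auc <- rep(NA_real_, K)
  roc <- vector("list", K)
  undefined <- integer(0)
  for (c in seq_len(K)) {
    pos <- y_true == (c - 1L)
    if (!any(pos) || all(pos)) {
      undefined <- c(undefined, c - 1L)
      next
    }
    s <- scores[, c]
    ord <- order(-s)
    lab <- pos[ord]
    # step through unique thresholds
    tps <- cumsum(lab); fps <- cumsum(!lab)
    keep <- c(diff(s[ord]) != 0, TRUE)
    tpr <- c(0, tps[keep] / sum(pos))
    fpr <- c(0, fps[keep] / sum(!pos))
    auc[c] <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
    roc[[c]] <- data.frame(fpr = fpr, tpr = tpr)
  }
  list(roc = roc, auc = auc, undefined = undefined)
}

#' One-way ANOVA across classifiers
#'
#' Tests whether mean cross-validated accuracy differs between classifiers.
#' Observations are per-fold accuracies (one column per classifier); the
#' standard decomposition gives `df_columns = C - 1`,
#' `df_error = N - C`, `df_total = N - 1`, with exact SS/df additivity.
#'
#' @param acc numeric matrix, rows = observations (folds), columns =
#'   classifiers. Unbalanced designs (NA cells) are handled by omitting the
#'   missing observations.
#' @return An object of class `anova_table`: a data frame with rows
#'   `Columns`, `Error`, `Total` and columns `SS`, `df`, `MS`, `F`, `p`.
#' @export
anova_across_classifiers <- function(acc) {
  stop_if_not(is.matrix(acc) && ncol(acc) >= 2, "need >= 2 classifiers")
  long <- data.frame(acc = as.vector(acc),
                     classifier = factor(rep(colnames(acc) %||%
                                               seq_len(ncol(acc)),
                                             each = nrow(acc))))
  long <- long[is.finite(long$acc), ]
  counts <- table(long$classifier)
  stop_if_not(all(counts >= 2), "need >= 2 observations per classifier")
  if (length(unique(counts)) > 1) {
    message("unbalanced observation counts; unbalanced one-way ANOVA used")
  }
  fit <- stats::lm(acc ~ classifier, data = long)
  a <- withCallingHandlers(stats::anova(fit), warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w))) {
      invokeRestart("muffleWarning")     # all accuracies equal; F set below
    }
  })
  ss_col <- a[["Sum Sq"]][1]; ss_err <- a[["Sum Sq"]][2]
  df_col <- a[["Df"]][1]; df_err <- a[["Df"]][2]
  f_val <- a[["F value"]][1]
  p_val <- a[["Pr(>F)"]][1]
  if (ss_col <= .Machine$double.eps * max(1, sum(long$acc^2))) {
    f_val <- 0; p_val <- 1            # no between-classifier variation
  }
  tab <- data.frame(
    source = c("Columns", "Error", "Total"),
    SS = c(ss_col, ss_err, ss_col + ss_err),
    df = c(df_col, df_err, df_col + df_err),
    MS = c(ss_col / df_col, ss_err / df_err, NA),
    F = c(f_val, NA, NA),
    p = c(p_val, NA, NA))
  structure(tab, class = c("anova_table", "data.frame"))
}

#' Repeated stratified cross-validation of the classifier battery
#'
#' For every classifier and repeat, each fold is held out in turn; metrics
#' are computed per repeat from the repeat's pooled test-fold confusion
#' matrix, then summarised as mean and variance over repeats. ROC/AUC uses
#' the pooled test-fold scores of the first repeat; the across-classifier
#' ANOVA uses the per-fold accuracies of the first repeat.
#'
#' @param x a [feature_matrix()].
#' @param classifiers character vector of classifier names.
#' @param n_folds,n_repeats folds per repeat and number of repeats.
#' @param seed integer seed (fold assignment).
#' @return An `evaluation_report`: per-classifier `metrics` (mean/var),
#'   summed `confusion`, `fold_accuracy` (repeat x fold matrix per
#'   classifier), `auc` (per-class + macro), `roc` points, and `anova`.
#' @export
cv_evaluate <- function(x, classifiers = classifier_names(), n_folds = 5L,
                        n_repeats = 5L, seed = 1L) {
  K <- length(unique(x$labels))
  folds <- stratified_folds(x$labels, n_folds, n_repeats, seed)
  metrics <- list(); conf <- list(); fold_acc <- list()
  auc <- list(); rocs <- list()
  for (cl in classifiers) {
    spec <- classifier_spec(cl)
    per_repeat <- matrix(NA_real_, n_repeats, 6,
                         dimnames = list(NULL, c("Accuracy", "Precision", "F1",
                                                 "Specificity", "MCC",
                                                 "Sensitivity")))
    fa <- matrix(NA_real_, n_repeats, n_folds)
    cm_sum <- matrix(0L, K, K)
    scores1 <- matrix(NA_real_, nrow(x$values), K)
    for (r in seq_len(n_repeats)) {
      cm_rep <- matrix(0L, K, K)
      for (f in seq_len(n_folds)) {
        test_idx <- folds[[r]][[f]]
        train_idx <- setdiff(seq_len(nrow(x$values)), test_idx)
        tr <- feature_matrix(x$values[train_idx, , drop = FALSE],
                             x$labels[train_idx], source = x$source,
                             network = x$network,
                             feature_names = x$feature_names)
        te <- feature_matrix(x$values[test_idx, , drop = FALSE],
                             x$labels[test_idx], source = x$source,
                             network = x$network,
                             feature_names = x$feature_names)
        pr <- fit_predict(spec, tr, te)
        cm_f <- confusion(x$labels[test_idx], pr$pred, K)
        cm_rep <- cm_rep + cm_f
        fa[r, f] <- sum(diag(cm_f)) / sum(cm_f)
        if (r == 1L) scores1[test_idx, ] <- pr$scores
      }
      per_repeat[r, ] <- metrics_from_confusion(cm_rep)$macro[
        colnames(per_repeat)]
      cm_sum <- cm_sum + cm_rep
    }
    ro <- roc_ovr(scores1, x$labels)
    metrics[[cl]] <- list(mean = colMeans(per_repeat),
                          var = apply(per_repeat, 2L, stats::var))
    conf[[cl]] <- cm_sum
    fold_acc[[cl]] <- fa
    auc[[cl]] <- ro$auc
    rocs[[cl]] <- ro$roc
  }
  first_rep_acc <- vapply(classifiers, function(cl) fold_acc[[cl]][1, ],
                          numeric(n_folds))
  an <- if (length(classifiers) >= 2) {
    anova_across_classifiers(as.matrix(first_rep_acc))
  } else NULL
  structure(list(metrics = metrics, confusion = conf, fold_accuracy = fold_acc,
                 auc = auc, roc = rocs, anova = an, n_folds = n_folds,
                 n_repeats = n_repeats, classifiers = classifiers),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %d classifiers, %d-fold x %d repeats\n",
              length(x$classifiers), x$n_folds, x$n_repeats))
  for (cl in x$classifiers) {
    cat(sprintf("  %-5s acc=%.4f (var %.2e) macroF1=%.4f MCC=%.4f\n", cl,
                x$metrics[[cl]]$mean[["Accuracy"]],
                x$metrics[[cl]]$var[["Accuracy"]],
                x$metrics[[cl]]$mean[["F1"]],
                x$metrics[[cl]]$mean[["MCC"]]))
  }
  invisible(x)
}

#' Export an evaluation report to CSV/JSON files
#'
#' Writes `metrics.csv` (classifier x metric, mean and variance),
#' per-classifier confusion CSVs, `anova.csv` and `summary.json` into `dir`.
#'
#' @param report a [cv_evaluate()] report.
#' @param dir output directory.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(report$classifiers, function(cl) {
    m <- report$metrics[[cl]]
    data.frame(classifier = cl, metric = names(m$mean),
               mean = as.numeric(m$mean), variance = as.numeric(m$var))
  })
  utils::write.csv(do.call(rbind, rows), file.path(dir, "metrics.csv"),
                   row.names = FALSE)
  for (cl in report$classifiers) {
    utils::write.csv(report$confusion[[cl]],
                     file.path(dir, sprintf("confusion_%s.csv", cl)))
  }
  if (!is.null(report$anova)) {
    utils::write.csv(as.data.frame(report$anova), file.path(dir, "anova.csv"),
                     row.names = FALSE)
  }
  summary <- lapply(report$classifiers, function(cl) {
    list(accuracy = report$metrics[[cl]]$mean[["Accuracy"]],
         macro_f1 = report$metrics[[cl]]$mean[["F1"]],
         mcc = report$metrics[[cl]]$mean[["MCC"]],
         auc = report$auc[[cl]])
  })
  names(summary) <- report$classifiers
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
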