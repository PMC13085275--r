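test_that("stratified folds partition and balance", {
  labels <- rep(0:4, each = 20)                    # balanced 100-sample 5-class
  folds <- stratified_folds(labels, n_folds = 5, n_repeats = 2, seed = 3)[[1]]
  expect_length(folds, 5)
  all_idx <- sort(unlist(folds))
  expect_identical(all_idx, seq_along(labels))     # union = everything
  for (f in folds) {
    expect_equal(as.integer(table(labels[f])), rep(4L, 5))  # exactly 4/class
  }
  for (i in 1:4) for (j in (i + 1):5) {
    expect_length(intersect(folds[[i]], folds[[j]]), 0)     # disjoint
  }
})

test_that("heavily imbalanced labels still give every class in every fold", {
  labels <- rep(0:3, c(613, 113, 163, 74))         # LBC-shaped composition
  folds <- stratified_folds(labels, n_folds = 5, seed = 1)[[1]]
  for (f in folds) {
    expect_setequal(unique(labels[f]), 0:3)
    tab <- table(factor(labels[f], levels = 0:3))
    global <- c(613, 113, 163, 74) / 5
    expect_true(all(abs(as.numeric(tab) - global) <= 1))    # +/- 1 sample
  }
  expect_error(stratified_folds(c(0, 0, 0, 1), n_folds = 5),
               "smaller than n_folds")
})

test_that("all seven classifiers solve well-separated blobs perfectly", {
  tr <- make_blobs(n_per = 15, sep = 10, seed = 5)
  te <- make_blobs(n_per = 6, sep = 10, seed = 6)
  for (cl in classifier_names()) {
    pr <- fit_predict(cl, tr, te)
    expect_equal(pr$pred, te$labels, label = cl)
    expect_equal(dim(pr$scores), c(12, 2))
  }
})

test_that("KNN unanimity and cosine scale invariance", {
  # a point replicated 10x in train forces the MKNN vote
  X <- rbind(matrix(rep(c(5, 5), 10), 10, 2, byrow = TRUE),
             matrix(rnorm(20, mean = -5), 10, 2))
  tr <- feature_matrix(X, rep(0:1, each = 10), source = "synthetic")
  te <- feature_matrix(matrix(c(5, 5), 1, 2), 0L, source = "synthetic")
  pr <- fit_predict("MKNN", tr, te)
  expect_equal(pr$pred, 0L)
  expect_equal(unname(pr$scores[1, "0"]), 1)

  # cosine KNN ignores positive per-row rescaling
  set.seed(30)
  tr2 <- make_blobs(n_per = 12, sep = 3, seed = 7)
  te2 <- make_blobs(n_per = 5, sep = 3, seed = 8)
  pr1 <- fit_predict("CKNN", tr2, te2)
  te_scaled <- feature_matrix(te2$values * runif(nrow(te2$values), 0.1, 9),
                              te2$labels, source = "synthetic")
  pr2 <- fit_predict("CKNN", tr2, te_scaled)
  expect_identical(pr1$pred, pr2$pred)
  expect_equal(pr1$scores, pr2$scores)
})

test_that("standardisation statistics never leak from the test fold", {
  tr <- make_blobs(n_per = 15, sep = 8, seed = 9)
  te_a <- make_blobs(n_per = 4, sep = 8, seed = 10)
  # canary: same rows plus wildly extreme extra test rows
  te_b <- feature_matrix(rbind(te_a$values, matrix(1e6, 2, ncol(te_a$values))),
                         c(te_a$labels, 0L, 0L), source = "synthetic")
  for (cl in c("LSVM", "MKNN", "LDA")) {
    pa <- fit_predict(cl, tr, te_a)$pred
    pb <- fit_predict(cl, tr, te_b)$pred[seq_along(pa)]
    expect_identical(pa, pb, label = cl)
  }
})

test_that("confusion matrices book-keep exactly", {
  y <- c(0, 0, 1, 1, 2, 2)
  cm <- confusion(y, y, 3)
  expect_equal(cm, diag(2L, 3), ignore_attr = TRUE)
  y_hat <- c(0, 1, 1, 0, 2, 2)
  cm2 <- confusion(y, y_hat, 3)
  expect_equal(rowSums(cm2), as.numeric(table(y)), ignore_attr = TRUE)
  # swapping two predicted labels transposes the off-diagonal cells
  y_swap <- c(1, 0, 0, 1, 2, 2)
  cm3 <- confusion(y, y_swap, 3)
  expect_equal(cm3[1, 2], cm2[2, 1])
  expect_equal(cm3[2, 1], cm2[1, 2])
  expect_error(confusion(c(0, 3), c(0, 0), 3), "out of range")
})

test_that("metric formulas match hand-computed values", {
  # perfect three-class prediction: every metric 1
  perfect <- metrics_from_confusion(diag(10L, 3))
  expect_equal(unname(perfect$macro),
               rep(1, length(perfect$macro)))
  expect_equal(perfect$per_class$MCC, rep(1, 3))

  # binary case [[40,10],[5,45]]: TP=40 FN=10 FP=5 TN=45 for class 0
  cm <- matrix(c(40L, 5L, 10L, 45L), 2, 2)
  m <- metrics_from_confusion(cm)
  c0 <- m$per_class[1, ]
  expect_equal(c0$Sensitivity, 0.8)
  expect_equal(c0$Specificity, 0.9)
  expect_equal(c0$Precision, 40 / 45)
  expect_equal(c0$Accuracy, 0.85)
  mcc_hand <- (40 * 45 - 5 * 10) / sqrt((40 + 5) * (40 + 10) * (45 + 5) * (45 + 10))
  expect_equal(c0$MCC, mcc_hand)
  expect_equal(c0$F1, 2 * 40 / (2 * 40 + 5 + 10))
})

test_that("F1 is the harmonic mean of precision and sensitivity", {
  set.seed(31)
  for (i in 1:10) {
    cm <- matrix(sample(0:30, 4, replace = TRUE), 2, 2)
    if (sum(cm) == 0) next
    m <- metrics_from_confusion(cm)
    for (c in 1:2) {
      pr <- m$per_class$Precision[c]; se <- m$per_class$Sensitivity[c]
      if (pr + se > 0) {
        expect_equal(m$per_class$F1[c], 2 * pr * se / (pr + se),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("random predictions give near-zero MCC", {
  set.seed(32)
  mccs <- replicate(40, {
    y <- rep(0:1, each = 50)
    p <- sample(0:1, 100, replace = TRUE)
    metrics_from_confusion(confusion(y, p, 2))$macro[["MCC"]]
  })
  expect_lt(abs(mean(mccs)), 0.05)
})

test_that("ROC/AUC behaves at its limits and under score reversal", {
  y <- rep(0:1, each = 10)
  s_perfect <- cbind(rev(seq_len(20)), seq_len(20))
  r <- roc_ovr(s_perfect, y)
  expect_equal(r$auc, c(1, 1))
  r_rev <- roc_ovr(-s_perfect, y)
  expect_equal(r_rev$auc, 1 - r$auc)
  # label-independent scores hover near 1/2
  set.seed(33)
  aucs <- replicate(30, roc_ovr(cbind(rnorm(40), rnorm(40)),
                                rep(0:1, each = 20))$auc[1])
  expect_lt(abs(mean(aucs) - 0.5), 0.06)
  # a class with no positives is flagged undefined
  r_one <- roc_ovr(cbind(rnorm(6), rnorm(6)), rep(0L, 6))
  expect_true(1 %in% r_one$undefined)
  expect_true(is.na(r_one$auc[2]))
})

test_that("the across-classifier ANOVA table has the canonical structure", {
  set.seed(34)
  acc <- matrix(0.9 + rnorm(35, sd = 0.01), 5, 7,
                dimnames = list(NULL, classifier_names()))
  tab <- anova_across_classifiers(acc)
  expect_equal(tab$df, c(6, 28, 34))
  expect_equal(tab$SS[3], tab$SS[1] + tab$SS[2], tolerance = 1e-12)
  # manual SS decomposition oracle
  grand <- mean(acc)
  ssb <- sum(5 * (colMeans(acc) - grand)^2)
  ssw <- sum(sweep(acc, 2, colMeans(acc))^2)
  expect_equal(tab$SS[1], ssb, tolerance = 1e-10)
  expect_equal(tab$SS[2], ssw, tolerance = 1e-10)
  expect_equal(tab$F[1], (ssb / 6) / (ssw / 28), tolerance = 1e-10)

  # identical accuracies: no between-classifier variation
  same <- matrix(0.5, 4, 3)
  tab0 <- anova_across_classifiers(same)
  expect_equal(tab0$SS[1], 0)
  expect_equal(tab0$F[1], 0)

  # two groups: F equals the squared pooled t statistic
  a <- rnorm(8, 0.8, 0.02); b <- rnorm(8, 0.85, 0.02)
  tab2 <- anova_across_classifiers(cbind(a = a, b = b))
  t2 <- t.test(a, b, var.equal = TRUE)$statistic^2
  expect_equal(tab2$F[1], unname(as.numeric(t2)), tolerance = 1e-10)
})

test_that("cross-validated reports are sane and tighten with separation", {
  g_hi <- generate_feature_matrix(synthetic_feature_spec(
    60, 10, 4, effect_size = 50, n_classes = 2, seed = 12))
  rep_hi <- cv_evaluate(g_hi$features, c("LSVM", "LDA"), n_folds = 3,
                        n_repeats = 3, seed = 3)
  expect_equal(rep_hi$metrics$LSVM$mean[["Accuracy"]], 1)
  expect_equal(rep_hi$metrics$LSVM$var[["Accuracy"]], 0)  # variance collapses
  expect_true(all(rep_hi$metrics$LDA$mean >= 0 & rep_hi$metrics$LDA$mean <= 1))
  expect_true(rep_hi$metrics$LDA$mean[["MCC"]] >= -1 &&
                rep_hi$metrics$LDA$mean[["MCC"]] <= 1)
  expect_equal(sum(rep_hi$confusion$LSVM), 60 * 3)        # summed over folds
  expect_true(all(rep_hi$auc$LSVM >= 0.99))
})
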