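test_that("network concatenation follows the fixed order with provenance", {
  labs <- rep(0:1, each = 3)
  mk <- function(p, net) feature_matrix(matrix(rnorm(6 * p), 6, p), labs,
                                        source = "fused", network = net)
  sets <- list(mk(256, "resnet18"), mk(640, "efficientnetb0"),
               mk(640, "mobilenet"))
  ens <- concat_networks(sets)
  expect_equal(ncol(ens$values), 1536)
  nets <- sub("\\..*$", "", ens$feature_names)
  expect_equal(rle(nets)$values, c("efficientnetb0", "mobilenet", "resnet18"))
  expect_equal(as.integer(rle(nets)$lengths), c(640L, 640L, 256L))
  # single set in, identity out
  one <- concat_networks(list(mk(10, "resnet18")))
  expect_equal(ncol(one$values), 10)
  # label mismatch refused
  bad <- feature_matrix(matrix(rnorm(6 * 4), 6, 4), rev(labs),
                        source = "fused", network = "mobilenet")
  expect_error(concat_networks(list(mk(4, "resnet18"), bad)), "label")
})

test_that("per-feature F-ratios agree with brute force and stats::aov", {
  set.seed(20)
  labs <- rep(0:2, each = 7)
  X <- matrix(rnorm(21 * 6), 21, 6)
  X[, 2] <- X[, 2] + labs * 1.5
  fm <- feature_matrix(X, labs, source = "synthetic")
  rk <- anova_f_scores(fm)
  for (j in 1:6) {
    a <- summary(stats::aov(X[, j] ~ factor(labs)))[[1]]
    expect_equal(rk$f_scores[j], a[["F value"]][1], tolerance = 1e-10)
    expect_equal(rk$p_values[j], a[["Pr(>F)"]][1], tolerance = 1e-10)
  }
  # brute-force SS decomposition oracle for one column
  j <- 2
  grand <- mean(X[, j])
  ssb <- sum(vapply(0:2, function(g) {
    sum(labs == g) * (mean(X[labs == g, j]) - grand)^2
  }, numeric(1)))
  ssw <- sum(vapply(0:2, function(g) {
    sum((X[labs == g, j] - mean(X[labs == g, j]))^2)
  }, numeric(1)))
  expect_equal(rk$f_scores[j], (ssb / 2) / (ssw / 18), tolerance = 1e-10)
})

test_that("two-class F equals the squared pooled-variance t statistic", {
  set.seed(21)
  labs <- rep(0:1, each = 9)
  x <- rnorm(18) + labs * 0.8
  fm <- feature_matrix(matrix(x, ncol = 1), labs, source = "synthetic")
  f <- anova_f_scores(fm)$f_scores
  t2 <- t.test(x[labs == 0], x[labs == 1], var.equal = TRUE)$statistic^2
  expect_equal(unname(f), unname(as.numeric(t2)), tolerance = 1e-10)
})

test_that("degenerate columns follow the documented F policy", {
  labs <- rep(0:1, each = 4)
  X <- cbind(perfect = c(rep(0, 4), rep(1, 4)),   # zero within-class variance
             const = rep(5, 8),                   # globally constant
             noise = c(0.3, -1, 0.5, 0.2, -0.7, 1.1, 0.4, -0.2))
  fm <- feature_matrix(X, labs, source = "synthetic")
  rk <- anova_f_scores(fm)
  expect_true(is.infinite(rk$f_scores[1]))
  expect_equal(rk$order[1], 1)                    # ranked first
  expect_equal(rk$f_scores[2], 0)
  expect_equal(rk$order[length(rk$order)], 2)     # ranked last
  expect_true(is.na(rk$p_values[2]))
  expect_equal(select_top_k(rk, 1), 1)
  # single-sample class refused
  fm_bad <- feature_matrix(X[1:5, ], c(0L, 0L, 0L, 0L, 1L),
                           source = "synthetic")
  expect_error(anova_f_scores(fm_bad), "single sample")
})

test_that("rankings are invariant to affine column rescaling", {
  set.seed(22)
  labs <- rep(0:1, each = 10)
  X <- matrix(rnorm(20 * 5), 20, 5) + labs * 0.5
  fm1 <- feature_matrix(X, labs, source = "synthetic")
  X2 <- sweep(sweep(X, 2, c(2, 0.5, 10, 1, 3), "*"), 2, c(-1, 5, 0, 2, 7), "+")
  fm2 <- feature_matrix(X2, labs, source = "synthetic")
  r1 <- anova_f_scores(fm1); r2 <- anova_f_scores(fm2)
  expect_equal(r1$f_scores, r2$f_scores, tolerance = 1e-9)
  expect_identical(r1$order, r2$order)
})

test_that("top-k selection bounds and determinism hold", {
  set.seed(23)
  labs <- rep(0:1, each = 5)
  fm <- feature_matrix(matrix(rnorm(10 * 7), 10, 7), labs, source = "synthetic")
  rk <- anova_f_scores(fm)
  expect_equal(select_top_k(rk, 7), 1:7)
  expect_identical(select_top_k(rk, 3), select_top_k(rk, 3))
  expect_error(select_top_k(rk, 0), "k must be")
  expect_error(select_top_k(rk, 8), "k must be")
})

test_that("the top-k sweep saturates rather than starving", {
  g <- generate_feature_matrix(synthetic_feature_spec(
    150, 300, 50, effect_size = 1.2, n_classes = 3, seed = 17))
  ens <- feature_matrix(g$features$values, g$labels, source = "ensemble",
                        network = "synthetic")
  sw <- sweep_k(ens, classifiers = "LSVM", grid = c(5, 50, 300),
                n_folds = 3, n_repeats = 1, seed = 2)
  expect_equal(dim(sw$accuracy), c(1, 3))
  acc <- sw$accuracy[1, ]
  expect_gte(acc[["50"]], acc[["5"]])    # enough features beat starvation
  # grid = p reduces to the no-selection evaluation
  full <- cv_evaluate(ens, "LSVM", n_folds = 3, n_repeats = 1, seed = 2)
  expect_equal(acc[["300"]], full$metrics$LSVM$mean[["Accuracy"]])
})

test_that("ranking export carries name, network, F, p and rank", {
  labs <- rep(0:1, each = 4)
  fm <- feature_matrix(matrix(rnorm(8 * 3), 8, 3), labs, source = "ensemble",
                       feature_names = c("mobilenet.f0", "mobilenet.f1",
                                         "resnet18.f0"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_ranking_csv(anova_f_scores(fm), path)
  df <- read.csv(path)
  expect_equal(names(df), c("feature_name", "network", "F", "p", "rank"))
  expect_setequal(df$rank, 1:3)
  expect_equal(df$network[1], "mobilenet")
})
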