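test_that("flattening is the row-major position unroll and round-trips", {
  C <- 5
  v <- rnorm(C)
  one <- array(v, dim = c(1, 1, C))
  expect_equal(as.numeric(flatten_map(one)), v)

  f <- array(rnorm(2 * 3 * 4), dim = c(2, 3, 4))
  x <- flatten_map(f)
  expect_equal(dim(x), c(6, 4))
  expect_equal(unflatten_seq(x, 2, 3), f)

  # independent nested-loop oracle for row ordering
  oracle <- matrix(0, 6, 4)
  for (i in 1:2) for (j in 1:3) oracle[(i - 1) * 3 + j, ] <- f[i, j, ]
  expect_equal(unname(x[, ]), oracle)
})

test_that("QKV projections are plain matrix products", {
  cfg <- attention_config(4, 2, 4)
  w <- attention_weights(cfg, seed = 2)
  x0 <- matrix(0, 3, 4)
  q0 <- project_qkv(x0, w)
  expect_true(all(q0$Q == 0) && all(q0$K == 0) && all(q0$V == 0))

  wI <- w; wI$W_Q <- diag(4)
  x <- matrix(rnorm(12), 3, 4)
  expect_equal(project_qkv(x, wI)$Q, x)

  # naive triple-loop oracle
  qkv <- project_qkv(x, w)
  oracle <- matrix(0, 3, 4)
  for (i in 1:3) for (j in 1:4) {
    for (k in 1:4) oracle[i, j] <- oracle[i, j] + x[i, k] * w$W_Q[k, j]
  }
  expect_equal(qkv$Q, oracle)
  expect_error(project_qkv(matrix(0, 3, 5), w), "channels")
})

test_that("scaled dot-product attention matches closed forms", {
  # N = 1: softmax of a scalar is 1, output is the value row
  q <- matrix(rnorm(3), 1); k <- matrix(rnorm(3), 1); v <- matrix(rnorm(3), 1)
  expect_equal(scaled_dot_attention(q, k, v), v)

  # zero keys: uniform weights, output = column means of V
  q <- matrix(rnorm(8), 4, 2); v <- matrix(rnorm(8), 4, 2)
  out <- scaled_dot_attention(q, matrix(0, 4, 2), v, return_weights = TRUE)
  expect_equal(attr(out, "weights"), matrix(0.25, 4, 4))
  expect_equal(out[1, ], colMeans(v))

  # 2x2 hand-evaluated scalar case
  q <- matrix(c(1, 0, 0, 1), 2, 2)
  k <- matrix(c(1, 0, 0, 1), 2, 2)
  v <- matrix(c(1, 2, 3, 4), 2, 2)
  s <- q %*% t(k) / sqrt(2)
  e11 <- exp(1 / sqrt(2)); e12 <- exp(0)
  a11 <- e11 / (e11 + e12); a12 <- e12 / (e11 + e12)
  hand <- rbind(c(a11 * v[1, 1] + a12 * v[2, 1], a11 * v[1, 2] + a12 * v[2, 2]),
                c(a12 * v[1, 1] + a11 * v[2, 1], a12 * v[1, 2] + a11 * v[2, 2]))
  expect_equal(scaled_dot_attention(q, k, v), hand, tolerance = 1e-12)

  expect_error(scaled_dot_attention(matrix(0, 2, 0), matrix(0, 2, 0),
                                    matrix(0, 2, 0)), "d_k")
})

test_that("attention weights always form row-stochastic matrices", {
  for (s in 1:5) {
    q <- matrix(rnorm(12, sd = 3), 4, 3)
    k <- matrix(rnorm(12, sd = 3), 4, 3)
    v <- matrix(rnorm(12), 4, 3)
    out <- scaled_dot_attention(q, k, v, return_weights = TRUE)
    expect_equal(rowSums(attr(out, "weights")), rep(1, 4), tolerance = 1e-12)
  }
})

test_that("multi-head attention reduces, slices and permutes correctly", {
  # h = 1 with identity W_O equals single-head attention on full Q, K, V
  cfg1 <- attention_config(4, 1, 4)
  w <- attention_weights(cfg1, seed = 3)
  w$W_O <- diag(4)
  x <- matrix(rnorm(20), 5, 4)
  qkv <- project_qkv(x, w)
  expect_equal(multi_head_attention(x, w, cfg1),
               scaled_dot_attention(qkv$Q, qkv$K, qkv$V),
               ignore_attr = TRUE)

  # h = 2 on a 4x4 case matches the explicit two-slice computation
  cfg2 <- attention_config(4, 2, 4)
  w2 <- attention_weights(cfg2, seed = 4)
  out <- multi_head_attention(x, w2, cfg2)
  qkv <- project_qkv(x, w2)
  h1 <- scaled_dot_attention(qkv$Q[, 1:2], qkv$K[, 1:2], qkv$V[, 1:2])
  h2 <- scaled_dot_attention(qkv$Q[, 3:4], qkv$K[, 3:4], qkv$V[, 3:4])
  expect_equal(out, cbind(h1, h2) %*% w2$W_O, ignore_attr = TRUE)

  # permutation equivariance (no positional encoding)
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(multi_head_attention(x[perm, ], w2, cfg2),
               multi_head_attention(x, w2, cfg2)[perm, ],
               ignore_attr = TRUE)

  # head reorder is undone by the matching W_O row permutation
  w_swap <- w2
  w_swap$W_Q <- w2$W_Q[, c(3, 4, 1, 2)]
  w_swap$W_K <- w2$W_K[, c(3, 4, 1, 2)]
  w_swap$W_V <- w2$W_V[, c(3, 4, 1, 2)]
  w_swap$W_O <- w2$W_O[c(3, 4, 1, 2), ]
  expect_equal(multi_head_attention(x, w_swap, cfg2), out,
               ignore_attr = TRUE)
})

test_that("identical rows stay identical through attention", {
  cfg <- attention_config(6, 2, 6)
  w <- attention_weights(cfg, seed = 5)
  x <- matrix(rep(rnorm(6), each = 8), 8, 6)
  out <- multi_head_attention(x, w, cfg)
  for (r in 2:8) expect_equal(out[r, ], out[1, ])
})

test_that("embedding bookkeeping enforces d = h * d_k", {
  expect_equal(attention_config(1280, 8)$head_dim, 160L)
  expect_equal(attention_config(512, 8)$head_dim, 64L)
  expect_equal(attention_config(16, 8)$head_dim, 2L)
  expect_error(attention_config(16, 5), "divisible")
})

test_that("cross entropy matches its closed forms", {
  expect_equal(cross_entropy(c(0, 1, 0), c(0, 1, 0)), 0)
  K <- 7
  expect_equal(cross_entropy(c(1, rep(0, K - 1)), rep(1 / K, K)), log(K))
  y <- c(0, 0, 1); yhat <- c(0.2, 0.3, 0.5)
  expect_equal(cross_entropy(y, yhat), -log(0.5))
  expect_warning(cross_entropy(c(1, 0), c(0, 1)), "zero probability")
})
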