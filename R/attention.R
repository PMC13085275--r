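# Multi-head scaled dot-product self-attention over CNN feature maps.
#
# An H x W x C activation block from the last convolutional stage is reshaped
# into a sequence X (N x C, N = H*W, row r = (i-1)*W + j for spatial (i,j)).
# Trainable projections W_Q, W_K, W_V (C x d) produce Q, K, V; the embedding
# dimension d is split over h heads (d = h * d_k, contiguous column blocks);
# each head computes softmax(Q_i K_i' / sqrt(d_k)) V_i; heads are concatenated
# and projected back to C channels by W_O (d x C). There is no positional
# encoding, so the operator is permutation-equivariant over positions.

#' Attention configuration
#'
#' @param channels `C`, channel count of the feature map the module sits on
#'   (1280 for the MobileNet / EfficientNetB0 stages, 512 for ResNet-18).
#' @param n_heads number of attention heads `h` (default 8).
#' @param embed_dim embedding dimension `d`; defaults to `channels` so the
#'   attention output keeps the backbone's channel count (`d = h * d_k`).
#' @return An object of class `attention_config` with fields `channels`,
#'   `n_heads`, `embed_dim`, `head_dim`.
#' @export
attention_config <- function(channels, n_heads = 8L, embed_dim = channels) {
  stop_if_not(channels > 0, "channels must be positive")
  stop_if_not(n_heads >= 1, "need at least one head")
  stop_if_not(embed_dim %% n_heads == 0,
              sprintf("embed_dim %d not divisible by n_heads %d", embed_dim, n_heads))
  d_k <- embed_dim %/% n_heads
  stop_if_not(d_k >= 1, "per-head dimension must be >= 1")
  structure(list(channels = as.integer(channels), n_heads = as.integer(n_heads),
                 embed_dim = as.integer(embed_dim), head_dim = as.integer(d_k)),
            class = "attention_config")
}

#' Initialise attention projection weights
#'
#' Xavier-uniform initialisation of `W_Q`, `W_K`, `W_V` (`C x d`) and `W_O`
#' (`d x C`).
#'
#' @param cfg an [attention_config()].
#' @param seed integer seed.
#' @return A list of the four matrices, class `attention_weights`.
#' @export
attention_weights <- function(cfg, seed = 1L) {
  C <- cfg$channels; d <- cfg$embed_dim
  with_seed(seed, {
    lim <- sqrt(6 / (C + d))
    w <- function(nr, nc) matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
    structure(list(W_Q = w(C, d), W_K = w(C, d), W_V = w(C, d), W_O = w(d, C)),
              class = "attention_weights")
  })
}

#' Flatten a feature map into a position sequence
#'
#' Row `r = (i-1)*W + j` of the output holds the channel vector at spatial
#' location `(i, j)`; columns preserve channel order.
#'
#' @param f an `H x W x C` numeric array.
#' @return An `N x C` matrix (`N = H*W`) with attributes `H`, `W`.
#' @export
flatten_map <- function(f) {
  stop_if_not(length(dim(f)) == 3, "expected an H x W x C array")
  h <- dim(f)[1]; w <- dim(f)[2]; C <- dim(f)[3]
  # row-major over (i, j): permute to (W, H, C) so unrolling is j-fastest
  x <- matrix(aperm(f, c(2, 1, 3)), h * w, C)
  attr(x, "H") <- h; attr(x, "W") <- w
  x
}

#' Restore a sequence into its feature map
#'
#' Inverse of [flatten_map()]; exact round-trip.
#'
#' @param x an `N x C` matrix.
#' @param h,w spatial size with `h * w == nrow(x)`.
#' @return An `H x W x C` array.
#' @export
unflatten_seq <- function(x, h = attr(x, "H"), w = attr(x, "W")) {
  stop_if_not(!is.null(h) && !is.null(w) && h * w == nrow(x),
              "h * w must equal the sequence length")
  C <- ncol(x)
  aperm(array(as.vector(x), dim = c(w, h, C)), c(2, 1, 3))
}

#' Project a sequence to queries, keys and values
#'
#' `Q = X W_Q`, `K = X W_K`, `V = X W_V`.
#'
#' @param x an `N x C` sequence.
#' @param w an [attention_weights()] list.
#' @return A list with `Q`, `K`, `V` (`N x d` each).
#' @export
project_qkv <- function(x, w) {
  stop_if_not(ncol(x) == nrow(w$W_Q),
              sprintf("sequence has %d channels but W_Q expects %d",
                      ncol(x), nrow(w$W_Q)))
  list(Q = x %*% w$W_Q, K = x %*% w$W_K, V = x %*% w$W_V)
}

#' Scaled dot-product attention for a single head
#'
#' `softmax(Q K' / sqrt(d_k)) V`, softmax applied row-wise.
#'
#' @param q,k,v `N x d_k` matrices.
#' @param return_weights also return the `N x N` attention-weight matrix.
#' @return The `N x d_k` attended values (attribute `"weights"` if requested).
#' @export
scaled_dot_attention <- function(q, k, v, return_weights = FALSE) {
  d_k <- ncol(q)
  stop_if_not(d_k >= 1, "d_k = 0 is invalid")
  stop_if_not(nrow(q) == nrow(k) && nrow(k) == nrow(v) &&
                ncol(k) == d_k && ncol(v) == d_k,
              "Q, K, V must share dimensions")
  a <- softmax_rows(q %*% t(k) / sqrt(d_k))
  out <- a %*% v
  if (return_weights) attr(out, "weights") <- a
  out
}

#' Multi-head self-attention
#'
#' Splits `Q`, `K`, `V` into `h` contiguous `d_k`-column blocks, attends each
#' head independently, concatenates and projects by `W_O` back to `C`
#' channels.
#'
#' @param x an `N x C` sequence.
#' @param w an [attention_weights()] list.
#' @param cfg an [attention_config()].
#' @return The `N x C` attention-enhanced sequence `SA(X)`.
#' @export
multi_head_attention <- function(x, w, cfg) {
  stop_if_not(cfg$embed_dim %% cfg$n_heads == 0, "d must be divisible by h")
  qkv <- project_qkv(x, w)
  d_k <- cfg$head_dim
  heads <- vector("list", cfg$n_heads)
  for (i in seq_len(cfg$n_heads)) {
    cols <- ((i - 1) * d_k + 1):(i * d_k)
    heads[[i]] <- scaled_dot_attention(qkv$Q[, cols, drop = FALSE],
                                       qkv$K[, cols, drop = FALSE],
                                       qkv$V[, cols, drop = FALSE])
  }
  out <- do.call(cbind, heads) %*% w$W_O
  attr(out, "H") <- attr(x, "H"); attr(out, "W") <- attr(x, "W")
  out
}

# Forward pass retaining everything the backward pass needs.
attention_forward <- function(x, w, cfg) {
  qkv <- project_qkv(x, w)
  d_k <- cfg$head_dim
  A <- vector("list", cfg$n_heads)     # per-head softmax weights
  H <- vector("list", cfg$n_heads)     # per-head outputs
  for (i in seq_len(cfg$n_heads)) {
    cols <- ((i - 1) * d_k + 1):(i * d_k)
    s <- qkv$Q[, cols, drop = FALSE] %*% t(qkv$K[, cols, drop = FALSE]) / sqrt(d_k)
    A[[i]] <- softmax_rows(s)
    H[[i]] <- A[[i]] %*% qkv$V[, cols, drop = FALSE]
  }
  concat <- do.call(cbind, H)
  list(out = concat %*% w$W_O, x = x, qkv = qkv, A = A, concat = concat)
}

# Backward pass: gradients w.r.t. the input sequence and the four projection
# matrices, given d(loss)/d(out).
attention_backward <- function(cache, dout, w, cfg) {
  d_k <- cfg$head_dim
  dW_O <- t(cache$concat) %*% dout
  dconcat <- dout %*% t(w$W_O)
  dQ <- matrix(0, nrow(cache$x), cfg$embed_dim)
  dK <- dQ; dV <- dQ
  for (i in seq_len(cfg$n_heads)) {
    cols <- ((i - 1) * d_k + 1):(i * d_k)
    dH <- dconcat[, cols, drop = FALSE]
    A <- cache$A[[i]]
    Vi <- cache$qkv$V[, cols, drop = FALSE]
    dA <- dH %*% t(Vi)
    dV[, cols] <- t(A) %*% dH
    # softmax row-wise Jacobian: dS = A * (dA - rowSums(dA * A))
    dS <- A * (dA - rowSums(dA * A))
    dQ[, cols] <- dS %*% cache$qkv$K[, cols, drop = FALSE] / sqrt(d_k)
    dK[, cols] <- t(dS) %*% cache$qkv$Q[, cols, drop = FALSE] / sqrt(d_k)
  }
  dx <- dQ %*% t(w$W_Q) + dK %*% t(w$W_K) + dV %*% t(w$W_V)
  list(dx = dx,
       dW_Q = t(cache$x) %*% dQ, dW_K = t(cache$x) %*% dK,
       dW_V = t(cache$x) %*% dV, dW_O = dW_O)
}

#' Categorical cross-entropy
#'
#' `-sum(y_c log yhat_c)` for a one-hot target and a probability vector.
#' Probabilities are clamped at `1e-12` before the log; a zero probability at
#' the true class is reported via a warning.
#'
#' @param y one-hot numeric vector.
#' @param yhat predicted probability vector (sums to 1 within tolerance).
#' @return Non-negative scalar loss.
#' @export
cross_entropy <- function(y, yhat) {
  stop_if_not(length(y) == length(yhat), "y and yhat lengths differ")
  stop_if_not(abs(sum(yhat) - 1) < 1e-6, "yhat must sum to 1")
  if (any(yhat[y > 0] <= 0)) {
    warning("zero probability at the true class; clamped to 1e-12")
  }
  -sum(y * log(pmax(yhat, .CYTODX_EPS)))
}
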