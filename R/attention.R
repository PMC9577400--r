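# Scaled dot-product attention, multi-head self-attention and bidirectional
# cross-attention. Tokens are rows: a modality's features form an L x d
# matrix. Forward passes are exported; the matching analytic backward passes
# (used by the SGD trainer) are internal and mirror the forward caches.

#' Scaled dot-product attention
#'
#' Computes `Softmax(Q K' / sqrt(d)) V` with the softmax applied row-wise
#' over key positions, using max-subtraction for numerical stability. Each
#' attention row sums to 1, so every output row is a convex combination of
#' the rows of `V`.
#'
#' @param Q Query matrix, `L_q x d`.
#' @param K Key matrix, `L_k x d`.
#' @param V Value matrix, `L_k x d_v`.
#' @param scale Scaling denominator; defaults to `sqrt(ncol(Q))`.
#' @return `L_q x d_v` matrix with the attention-weight matrix attached as
#'   attribute `"weights"`.
#' @export
scaled_dot_attention <- function(Q, K, V, scale = sqrt(ncol(Q))) {
  Q <- as.matrix(Q); K <- as.matrix(K); V <- as.matrix(V)
  stopifnot_finite(Q, "Q"); stopifnot_finite(K, "K"); stopifnot_finite(V, "V")
  if (ncol(Q) != ncol(K)) stop("Q and K must share the feature dimension")
  if (nrow(K) != nrow(V)) stop("K and V must have the same number of rows")
  A <- softmax_rows(Q %*% t(K) / scale)
  out <- A %*% V
  attr(out, "weights") <- A
  out
}

# One attention head forward with cache for the backward pass.
attn_head_fwd <- function(Q, K, V, scale) {
  A <- softmax_rows(Q %*% t(K) / scale)
  list(out = A %*% V, A = A)
}

# Backward of one head: gradients w.r.t. Q, K, V given d(out).
attn_head_bwd <- function(dout, Q, K, V, A, scale) {
  dV <- t(A) %*% dout
  dA <- dout %*% t(V)
  dS <- A * (dA - rowSums(dA * A)) # softmax Jacobian, row-wise
  list(dQ = dS %*% K / scale, dK = t(dS) %*% Q / scale, dV = dV)
}

#' Attention projection parameters
#'
#' Bundles the query/key/value projection matrices of one (multi-head)
#' attention block. All heads are fused: each matrix is `d_in x d_out` and
#' `d_out` is split evenly across heads, so head `h` scales by
#' `sqrt(d_out / n_heads)`.
#'
#' @param W_q,W_k,W_v Projection matrices of equal dimension.
#' @param n_heads Number of attention heads; must divide `ncol(W_q)`.
#' @return An object of class `attention_params`.
#' @export
attention_params <- function(W_q, W_k, W_v, n_heads = 1L) {
  stopifnot(all(dim(W_q) == dim(W_k)), all(dim(W_q) == dim(W_v)))
  if (ncol(W_q) %% n_heads != 0) stop("d_out must be divisible by n_heads")
  structure(list(W_q = W_q, W_k = W_k, W_v = W_v, n_heads = as.integer(n_heads)),
            class = "attention_params")
}

head_cols <- function(d_out, n_heads) {
  d_head <- d_out %/% n_heads
  lapply(seq_len(n_heads), function(h) ((h - 1L) * d_head + 1L):(h * d_head))
}

# Generic multi-head attention: Q and V are projected from x_qv, K from x_k.
# Self-attention passes x_qv = x_k; cross-attention passes the two
# modalities. Returns output plus cache when requested.
mha_fwd <- function(x_qv, x_k, params, cache = FALSE) {
  W_q <- params$W_q; W_k <- params$W_k; W_v <- params$W_v
  n_heads <- params$n_heads %||% 1L
  Q <- x_qv %*% W_q
  K <- x_k %*% W_k
  V <- x_qv %*% W_v
  cols <- head_cols(ncol(W_q), n_heads)
  scale <- sqrt(length(cols[[1]]))
  out <- matrix(0, nrow(Q), ncol(W_q))
  heads <- vector("list", n_heads)
  for (h in seq_len(n_heads)) {
    cc <- cols[[h]]
    r <- attn_head_fwd(Q[, cc, drop = FALSE], K[, cc, drop = FALSE],
                       V[, cc, drop = FALSE], scale)
    out[, cc] <- r$out
    heads[[h]] <- r$A
  }
  if (!cache) return(out)
  list(out = out, Q = Q, K = K, V = V, A = heads, cols = cols, scale = scale,
       x_qv = x_qv, x_k = x_k)
}

# Backward of mha_fwd. Returns gradients for the projections and both inputs.
mha_bwd <- function(dout, cache, params) {
  Q <- cache$Q; K <- cache$K; V <- cache$V
  dQ <- dK <- dV <- matrix(0, nrow(Q), ncol(Q))
  for (h in seq_along(cache$cols)) {
    cc <- cache$cols[[h]]
    g <- attn_head_bwd(dout[, cc, drop = FALSE],
                       Q[, cc, drop = FALSE], K[, cc, drop = FALSE],
                       V[, cc, drop = FALSE], cache$A[[h]], cache$scale)
    dQ[, cc] <- g$dQ; dK[, cc] <- g$dK; dV[, cc] <- g$dV
  }
  list(
    dW_q = t(cache$x_qv) %*% dQ,
    dW_k = t(cache$x_k) %*% dK,
    dW_v = t(cache$x_qv) %*% dV,
    dx_qv = dQ %*% t(params$W_q) + dV %*% t(params$W_v),
    dx_k = dK %*% t(params$W_k)
  )
}

#' Intra-modality multi-head self-attention
#'
#' Projects a token sequence to per-head queries, keys and values drawn from
#' the same modality, applies scaled dot-product attention per head with the
#' per-head key dimension as scale, and concatenates head outputs. With
#' `residual_layernorm = TRUE` the output is `layer_norm(x + attention)`;
#' the default returns the raw attention output.
#'
#' @param x Token sequence, `L x d_in` matrix.
#' @param params An [attention_params()] object.
#' @param residual_layernorm Apply a residual connection plus token-wise
#'   layer normalization (requires `d_in == d_out`).
#' @return `L x d_out` matrix.
#' @export
self_attention <- function(x, params, residual_layernorm = FALSE) {
  x <- as.matrix(x)
  stopifnot_finite(x, "x")
  out <- mha_fwd(x, x, params)
  if (residual_layernorm) out <- layer_norm(x + out)
  out
}

#' Inter-modality cross-attention (one path)
#'
#' Query and Value are projected from `qv_source`; Key is projected from
#' `k_source`, so the other modality decides how this modality's value rows
#' are re-weighted. The two paths of the bidirectional fusion module are two
#' calls with the modalities swapped (and separate parameters).
#'
#' @param qv_source Token sequence providing Query and Value, `L x d_in`.
#' @param k_source Token sequence providing Key, `L x d_in` (same token
#'   count as `qv_source`).
#' @inheritParams self_attention
#' @return `L x d_out` matrix.
#' @export
cross_attention <- function(qv_source, k_source, params,
                            residual_layernorm = FALSE) {
  qv_source <- as.matrix(qv_source); k_source <- as.matrix(k_source)
  stopifnot_finite(qv_source, "qv_source"); stopifnot_finite(k_source, "k_source")
  if (nrow(qv_source) != nrow(k_source)) {
    stop("cross-attention requires equal token counts (got ",
         nrow(qv_source), " vs ", nrow(k_source), ")")
  }
  out <- mha_fwd(qv_source, k_source, params)
  if (residual_layernorm) out <- layer_norm(qv_source + out)
  out
}

# Token-wise layer normalization (no learned gain/bias).
layer_norm <- function(x, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  sd <- sqrt(rowMeans(xc^2) + eps)
  xc / sd
}

# Backward of layer_norm given cached input.
layer_norm_bwd <- function(dout, x, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  sd <- sqrt(rowMeans(xc^2) + eps)
  y <- xc / sd
  (dout - rowMeans(dout) - y * rowMeans(dout * y)) / sd
}
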