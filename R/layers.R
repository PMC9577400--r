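# Low-level trainable layers with hand-written backward passes. Feature maps
# are stored as (H*W) x C matrices in column-major spatial order; images
# enter as H x W x 3 arrays with values in [0, 1].

# Fan-in-scaled uniform initialization (the standard default for linear and
# convolutional layers).
init_weight <- function(d_in, d_out) {
  lim <- 1 / sqrt(d_in)
  matrix(stats::runif(d_in * d_out, -lim, lim), d_in, d_out)
}

init_dense <- function(d_in, d_out) {
  list(W = init_weight(d_in, d_out), b = numeric(d_out))
}

add_row_vec <- function(m, v) m + rep(v, each = nrow(m))

dense_fwd <- function(x, p) add_row_vec(x %*% p$W, p$b)

dense_bwd <- function(dout, x, p) {
  list(dW = t(x) %*% dout, db = colSums(dout), dx = dout %*% t(p$W))
}

relu <- function(x) (x > 0) * x
relu_bwd <- function(dout, x) dout * (x > 0)

# --- convolution ------------------------------------------------------------
# Same-padding k x k convolution implemented as a gather (im2col) plus one
# matrix product. The gather indices depend only on the spatial geometry, so
# they are precomputed once per architecture; index 0 addresses an implicit
# zero slot (zero padding).

conv_indices <- function(h, w, c_in, k = 3L) {
  r <- (k - 1L) %/% 2L
  ij <- expand.grid(i = seq_len(h), j = seq_len(w)) # column-major cell order
  off <- expand.grid(di = -r:r, dj = -r:r)
  n_off <- nrow(off)
  idx <- matrix(0L, h * w, n_off * c_in)
  for (t in seq_len(n_off)) {
    ii <- ij$i + off$di[t]
    jj <- ij$j + off$dj[t]
    inside <- ii >= 1L & ii <= h & jj >= 1L & jj <= w
    base <- ifelse(inside, ii + (jj - 1L) * h, 0L)
    for (c in seq_len(c_in)) {
      col <- (c - 1L) * n_off + t
      idx[, col] <- ifelse(base > 0L, base + (c - 1L) * h * w, 0L)
    }
  }
  idx
}

init_conv <- function(h, w, c_in, c_out, k = 3L) {
  list(W = init_weight(k * k * c_in, c_out), b = numeric(c_out))
}

# x: (h*w*c_in) numeric vector (flattened H x W x C array). Returns list with
# the (h*w) x c_out output and the gathered patch matrix for backward.
conv_fwd <- function(x, p, idx) {
  patches <- matrix(c(0, x)[idx + 1L], nrow = nrow(idx))
  out <- add_row_vec(patches %*% p$W, p$b)
  list(out = out, patches = patches)
}

# Gather indices for the backward pass: input position p at kernel offset t
# is read by exactly one output cell (or none, near the border), so the
# scatter-add transpose of the convolution is itself a gather. Entries are
# linear indices into the (H*W) x (k*k*c_in) patch-gradient matrix; 0 means
# no contribution.
conv_back_indices <- function(h, w, c_in, k = 3L) {
  r <- (k - 1L) %/% 2L
  ij <- expand.grid(i = seq_len(h), j = seq_len(w))
  off <- expand.grid(di = -r:r, dj = -r:r)
  n_off <- nrow(off)
  hw <- h * w
  bidx <- matrix(0L, hw * c_in, n_off)
  for (t in seq_len(n_off)) {
    oi <- ij$i - off$di[t]
    oj <- ij$j - off$dj[t]
    inside <- oi >= 1L & oi <= h & oj >= 1L & oj <= w
    q <- ifelse(inside, oi + (oj - 1L) * h, 0L)
    for (c in seq_len(c_in)) {
      col_in_dpatch <- (c - 1L) * n_off + t
      rows <- (c - 1L) * hw + seq_len(hw)
      bidx[rows, t] <- ifelse(q > 0L, q + (col_in_dpatch - 1L) * hw, 0L)
    }
  }
  bidx
}

conv_bwd <- function(dout, cache, p, bidx) {
  dW <- t(cache$patches) %*% dout
  db <- colSums(dout)
  dpatch <- dout %*% t(p$W)
  dx <- rowSums(matrix(c(0, dpatch)[bidx + 1L], nrow = nrow(bidx)))
  list(dW = dW, db = db, dx = dx)
}

# --- average pooling --------------------------------------------------------
# s x s non-overlapping average pooling on an (h*w) x C feature-map matrix.
# pool_groups maps each input cell to its output cell; pool_members lists,
# per output cell, its s*s input cells (both precomputed; the forward is a
# sum of s*s row gathers, the backward one row gather).

pool_groups <- function(h, w, s) {
  ij <- expand.grid(i = seq_len(h), j = seq_len(w))
  oi <- (ij$i - 1L) %/% s + 1L
  oj <- (ij$j - 1L) %/% s + 1L
  oi + (oj - 1L) * (h %/% s)
}

pool_members <- function(h, w, s) {
  g <- pool_groups(h, w, s)
  m <- matrix(0L, (h %/% s) * (w %/% s), s * s)
  for (p in seq_len(nrow(m))) m[p, ] <- which(g == p)
  m
}

avgpool_fwd <- function(x, members, s) {
  acc <- x[members[, 1L], , drop = FALSE]
  for (t in 2L:ncol(members)) acc <- acc + x[members[, t], , drop = FALSE]
  acc / (s * s)
}

avgpool_bwd <- function(dout, groups, s) {
  dout[groups, , drop = FALSE] / (s * s)
}
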