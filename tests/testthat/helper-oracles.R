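# Independent brute-force oracles used to validate the vectorized
# implementations. Deliberately written as explicit scalar loops.

# Scaled dot-product attention via three nested loops and a scalar softmax.
loop_attention <- function(Q, K, V, scale = sqrt(ncol(Q))) {
  Lq <- nrow(Q); Lk <- nrow(K); dv <- ncol(V)
  out <- matrix(0, Lq, dv)
  for (i in seq_len(Lq)) {
    logits <- numeric(Lk)
    for (j in seq_len(Lk)) {
      s <- 0
      for (t in seq_len(ncol(Q))) s <- s + Q[i, t] * K[j, t]
      logits[j] <- s / scale
    }
    w <- exp(logits - max(logits))
    w <- w / sum(w)
    for (c in seq_len(dv)) {
      for (j in seq_len(Lk)) out[i, c] <- out[i, c] + w[j] * V[j, c]
    }
  }
  out
}

# Multi-head attention oracle: project, split columns per head, run the
# loop oracle per head, concatenate.
loop_multihead <- function(x_qv, x_k, W_q, W_k, W_v, n_heads) {
  Q <- x_qv %*% W_q; K <- x_k %*% W_k; V <- x_qv %*% W_v
  d_head <- ncol(W_q) / n_heads
  out <- NULL
  for (h in seq_len(n_heads)) {
    cols <- ((h - 1) * d_head + 1):(h * d_head)
    out <- cbind(out, loop_attention(Q[, cols, drop = FALSE],
                                     K[, cols, drop = FALSE],
                                     V[, cols, drop = FALSE],
                                     scale = sqrt(d_head)))
  }
  out
}

# Aggregated pairwise AUC via an exhaustive double loop over sample pairs.
brute_aggregated_auc <- function(probs, labels) {
  y <- as.integer(labels)
  present <- sort(unique(y))
  pair_vals <- c()
  for (a in seq_along(present)) {
    for (b in seq_along(present)) {
      if (b <= a) next
      i <- present[a]; j <- present[b]
      auc_dir <- function(pos, neg, col) {
        tot <- 0; cnt <- 0
        for (p in which(y == pos)) {
          for (q in which(y == neg)) {
            cnt <- cnt + 1
            if (probs[p, col] > probs[q, col]) tot <- tot + 1
            else if (probs[p, col] == probs[q, col]) tot <- tot + 0.5
          }
        }
        tot / cnt
      }
      pair_vals <- c(pair_vals, (auc_dir(i, j, i) + auc_dir(j, i, j)) / 2)
    }
  }
  mean(pair_vals)
}

# Deterministic probability rows for tests: softmax of a seeded score matrix.
random_prediction_set <- function(n, seed, informative = TRUE) {
  withr::with_seed(seed, {
    y <- sample(1:6, n, replace = TRUE)
    scores <- matrix(rnorm(n * 6), n, 6)
    if (informative) scores[cbind(seq_len(n), y)] <- scores[cbind(seq_len(n), y)] + 1.5
    probs <- t(apply(scores, 1, function(r) exp(r) / sum(exp(r))))
    prediction_set(probs, y)
  })
}

tiny_config <- function(...) {
  fusion_config(d_model = 8L, n_tokens = 2L, n_heads = 2L, image_size = 16L,
                meta_hidden_sizes = 8L, ...)
}

random_image <- function(size = 16L, seed = 1L) {
  withr::with_seed(seed, array(runif(size * size * 3), c(size, size, 3L)))
}
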