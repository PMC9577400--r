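# The multimodal fusion network: image encoder, metadata encoder,
# intra-modality self-attention, bidirectional inter-modality
# cross-attention, concatenation and a six-class softmax classifier.
#
# Both encoders emit token sequences of equal length n_tokens and width
# d_model, which makes every attention formula well-defined for both
# modalities; n_tokens = 1 recovers the degenerate single-vector reading.

#' Architecture configuration of the fusion network
#'
#' @param d_model Token width shared by both modalities (divisible by
#'   `n_heads`).
#' @param n_tokens Tokens per modality; the image grid cell count
#'   (`(image_size/8)^2`) must be divisible by it.
#' @param n_heads Attention heads.
#' @param use_self_attention Apply intra-modality self-attention to each
#'   modality (ablation switch).
#' @param use_cross_attention Apply the bidirectional inter-modality
#'   cross-attention paths (ablation switch). With both switches off the
#'   model reduces to the plain feature-concatenation baseline.
#' @param use_meta Include the metadata branch; `FALSE` gives the
#'   image-only baseline architecture.
#' @param use_residual_layernorm Wrap each attention block in a residual
#'   connection plus token-wise layer normalization.
#' @param backbone Image encoder: `"tiny_cnn"` (built-in CPU-scale
#'   convolutional stack) — a `"resnet50"`-scale backbone is outside this
#'   package's scope and is rejected with an error.
#' @param image_size Input image side length in pixels (divisible by 8);
#'   the tiny CNN downsamples by 8.
#' @param img_mean,img_sd Per-channel pixel normalization applied before
#'   the backbone (`(x - mean) / sd`); defaults suit skin photographs.
#' @param meta_hidden_sizes Hidden-layer widths of the metadata MLP.
#' @param conv_channels Channel counts of the two convolution stages.
#' @param normalize_meta Standardize numeric metadata on the training fold
#'   (off keeps raw values).
#' @param class_weights Weight the cross-entropy loss by inverse class
#'   frequency.
#' @param seed Parameter-initialization seed (logged in the model object).
#' @return An object of class `fusion_config`.
#' @export
fusion_config <- function(d_model = 64L, n_tokens = 8L, n_heads = 4L,
                          use_self_attention = TRUE, use_cross_attention = TRUE,
                          use_meta = TRUE, use_residual_layernorm = FALSE,
                          backbone = c("tiny_cnn", "resnet50"),
                          image_size = 64L, meta_hidden_sizes = 64L,
                          conv_channels = c(8L, 16L),
                          img_mean = c(0.75, 0.55, 0.45), img_sd = 0.2,
                          normalize_meta = FALSE, class_weights = FALSE,
                          seed = 1L) {
  backbone <- match.arg(backbone)
  d_model <- as.integer(d_model); n_tokens <- as.integer(n_tokens)
  n_heads <- as.integer(n_heads); image_size <- as.integer(image_size)
  if (d_model %% n_heads != 0) stop("d_model must be divisible by n_heads")
  if (image_size %% 8L != 0) stop("image_size must be divisible by 8")
  n_cells <- (image_size %/% 8L)^2
  if (n_cells %% n_tokens != 0) {
    stop("(image_size/8)^2 = ", n_cells, " must be divisible by n_tokens")
  }
  structure(list(
    d_model = d_model, n_tokens = n_tokens, n_heads = n_heads,
    use_self_attention = isTRUE(use_self_attention),
    use_cross_attention = isTRUE(use_cross_attention),
    use_meta = isTRUE(use_meta),
    use_residual_layernorm = isTRUE(use_residual_layernorm),
    backbone = backbone, image_size = image_size,
    img_mean = rep_len(img_mean, 3L), img_sd = rep_len(img_sd, 3L),
    meta_hidden_sizes = as.integer(meta_hidden_sizes),
    conv_channels = as.integer(conv_channels),
    normalize_meta = isTRUE(normalize_meta),
    class_weights = isTRUE(class_weights),
    seed = as.integer(seed)
  ), class = "fusion_config")
}

#' Ablation and baseline variants of a configuration
#'
#' Maps a variant name to the corresponding switch settings: `"full"` (both
#' attention stages), `"no_self"` (without intra-modality self-attention),
#' `"no_cross"` (without inter-modality cross-attention), `"concat"` (plain
#' feature concatenation of the two encoders) and `"image_only"` (no
#' metadata branch).
#'
#' @param config A [fusion_config()].
#' @param variant One of `"full"`, `"no_self"`, `"no_cross"`, `"concat"`,
#'   `"image_only"`.
#' @return A modified [fusion_config()].
#' @export
variant_config <- function(config,
                           variant = c("full", "no_self", "no_cross",
                                       "concat", "image_only")) {
  variant <- match.arg(variant)
  switch(variant,
    full = config,
    no_self = { config$use_self_attention <- FALSE; config },
    no_cross = { config$use_cross_attention <- FALSE; config },
    concat = {
      config$use_self_attention <- FALSE
      config$use_cross_attention <- FALSE
      config
    },
    image_only = {
      config$use_meta <- FALSE
      config$use_self_attention <- FALSE
      config$use_cross_attention <- FALSE
      config
    })
}

# Fixed, non-trainable architecture data (gather indices, pooling groups).
# The tiny CNN downsamples by 8 in three stages: a fixed 2x2 average-pool
# stem, then two conv(3x3)+ReLU+avgpool(2x2) stages.
build_arch <- function(config) {
  s <- config$image_size
  c1 <- config$conv_channels[1]; c2 <- config$conv_channels[2]
  s1 <- s %/% 2L; s2 <- s %/% 4L; s3 <- s %/% 8L
  n_cells <- s3 * s3
  list(
    groups0 = pool_groups(s, s, 2L), members0 = pool_members(s, s, 2L),
    idx1 = conv_indices(s1, s1, 3L), bidx1 = conv_back_indices(s1, s1, 3L),
    groups1 = pool_groups(s1, s1, 2L), members1 = pool_members(s1, s1, 2L),
    idx2 = conv_indices(s2, s2, c1), bidx2 = conv_back_indices(s2, s2, c1),
    groups2 = pool_groups(s2, s2, 2L), members2 = pool_members(s2, s2, 2L),
    s = s, s1 = s1, s2 = s2,
    c1 = c1, c2 = c2, n_cells = n_cells,
    cells_per_token = n_cells %/% config$n_tokens,
    token_groups = rep(seq_len(config$n_tokens),
                       each = n_cells %/% config$n_tokens)
  )
}

init_attention_block <- function(d) {
  list(W_q = init_weight(d, d), W_k = init_weight(d, d), W_v = init_weight(d, d))
}

classifier_input_dim <- function(config) {
  (if (config$use_meta) 2L else 1L) * config$n_tokens * config$d_model
}

#' Build an (untrained) multimodal fusion model
#'
#' Initializes all trainable parameters with fan-in-scaled uniform draws
#' under `config$seed`. The parameter tree contains exactly the groups the
#' switches call for: disabling self- or cross-attention removes those
#' projection matrices from the trainable set, and `use_meta = FALSE`
#' removes the metadata encoder and both cross-attention paths.
#'
#' @param config A [fusion_config()].
#' @param meta_width Encoded metadata vector length (see
#'   [build_default_schema()]); ignored when `config$use_meta` is `FALSE`.
#' @return An object of class `mmf_model` with fields `params`, `config`,
#'   `arch` and `meta_width`.
#' @export
mmf_model <- function(config = fusion_config(), meta_width = NULL) {
  stopifnot(inherits(config, "fusion_config"))
  if (config$backbone == "resnet50") {
    stop("the resnet50-scale backbone is outside this package's scope; ",
         "use backbone = \"tiny_cnn\"")
  }
  if (config$use_meta && is.null(meta_width)) {
    stop("meta_width is required when the metadata branch is enabled")
  }
  arch <- build_arch(config)
  d <- config$d_model; L <- config$n_tokens
  params <- withr::with_seed(config$seed, {
    p <- list(img = list(
      conv1 = init_conv(arch$s1, arch$s1, 3L, arch$c1),
      conv2 = init_conv(arch$s2, arch$s2, arch$c1, arch$c2),
      proj = init_dense(arch$c2, d)
    ))
    if (config$use_meta) {
      sizes <- c(as.integer(meta_width), config$meta_hidden_sizes, L * d)
      p$meta <- lapply(seq_len(length(sizes) - 1L), function(i) {
        init_dense(sizes[i], sizes[i + 1L])
      })
    }
    if (config$use_self_attention) {
      p$self_img <- init_attention_block(d)
      if (config$use_meta) p$self_meta <- init_attention_block(d)
    }
    if (config$use_meta && config$use_cross_attention) {
      p$cross_img <- init_attention_block(d)
      p$cross_meta <- init_attention_block(d)
    }
    p$cls <- init_dense(classifier_input_dim(config), 6L)
    p
  })
  structure(list(params = params, config = config, arch = arch,
                 meta_width = if (config$use_meta) as.integer(meta_width) else 0L),
            class = "mmf_model")
}

as_attention_params <- function(block, n_heads) {
  attention_params(block$W_q, block$W_k, block$W_v, n_heads)
}

# Flatten a token sequence token-major (token 1's features first).
flatten_tokens <- function(x) as.vector(t(x))

# --- image encoder ----------------------------------------------------------

image_to_vec <- function(image, config) {
  if (length(dim(image)) != 3L || dim(image)[3] != 3L) {
    stop("image must be an H x W x 3 array")
  }
  if (any(dim(image)[1:2] != config$image_size)) {
    stop("image must be ", config$image_size, "x", config$image_size,
         " (preprocess/resize first)")
  }
  stopifnot_finite(image, "image")
  # channel normalization before the backbone
  npix <- config$image_size^2
  (as.numeric(image) - rep(config$img_mean, each = npix)) /
    rep(config$img_sd, each = npix)
}

encode_image_fwd <- function(x, params, arch, config, cache = FALSE) {
  p0 <- avgpool_fwd(matrix(x, ncol = 3L), arch$members0, 2L)
  c1 <- conv_fwd(as.vector(p0), params$img$conv1, arch$idx1)
  a1 <- relu(c1$out)
  p1 <- avgpool_fwd(a1, arch$members1, 2L)
  c2 <- conv_fwd(as.vector(p1), params$img$conv2, arch$idx2)
  a2 <- relu(c2$out)
  p2 <- avgpool_fwd(a2, arch$members2, 2L)
  proj <- dense_fwd(p2, params$img$proj)
  tokens <- rowsum(proj, arch$token_groups) / arch$cells_per_token
  if (!cache) return(tokens)
  list(tokens = tokens, c1 = c1, a1_in = c1$out, p1 = p1,
       c2 = c2, a2_in = c2$out, p2 = p2)
}

encode_image_bwd <- function(dtokens, fw, params, arch) {
  dproj <- dtokens[arch$token_groups, , drop = FALSE] / arch$cells_per_token
  g_proj <- dense_bwd(dproj, fw$p2, params$img$proj)
  da2 <- avgpool_bwd(g_proj$dx, arch$groups2, 2L)
  dc2 <- relu_bwd(da2, fw$a2_in)
  g_c2 <- conv_bwd(dc2, fw$c2, params$img$conv2, arch$bidx2)
  da1 <- avgpool_bwd(matrix(g_c2$dx, nrow = nrow(fw$p1)), arch$groups1, 2L)
  dc1 <- relu_bwd(da1, fw$a1_in)
  g_c1 <- conv_bwd(dc1, fw$c1, params$img$conv1, arch$bidx1)
  list(conv1 = list(W = g_c1$dW, b = g_c1$db),
       conv2 = list(W = g_c2$dW, b = g_c2$db),
       proj = list(W = g_proj$dW, b = g_proj$db))
}

#' Encode an image as a token sequence
#'
#' Runs the convolutional backbone: a fixed 2x2 average-pool stem followed
#' by two 3x3 same-padding convolution + ReLU + 2x2 average-pool stages
#' (downsampling by 8 in total), a learned linear projection of each
#' spatial cell to `d_model`, and adaptive average pooling of the cell
#' grid to `n_tokens` tokens.
#'
#' @param model An [mmf_model()] (or fitted [mmf_net()]).
#' @param image `image_size x image_size x 3` array, values in `[0, 1]`.
#' @return `n_tokens x d_model` token matrix.
#' @export
encode_image <- function(model, image) {
  x <- image_to_vec(image, model$config)
  encode_image_fwd(x, model$params, model$arch, model$config)
}

# --- metadata encoder -------------------------------------------------------

encode_meta_fwd <- function(meta, params, config, cache = FALSE) {
  layers <- params$meta
  n <- length(layers)
  acts <- vector("list", n + 1L)
  acts[[1]] <- matrix(meta, nrow = 1L)
  pre <- vector("list", n)
  for (i in seq_len(n)) {
    pre[[i]] <- dense_fwd(acts[[i]], layers[[i]])
    acts[[i + 1L]] <- if (i < n) relu(pre[[i]]) else pre[[i]]
  }
  tokens <- matrix(acts[[n + 1L]], nrow = config$n_tokens, byrow = TRUE)
  if (!cache) return(tokens)
  list(tokens = tokens, acts = acts, pre = pre)
}

encode_meta_bwd <- function(dtokens, fw, params) {
  layers <- params$meta
  n <- length(layers)
  grads <- vector("list", n)
  d <- matrix(flatten_tokens(dtokens), nrow = 1L)
  for (i in rev(seq_len(n))) {
    if (i < n) d <- relu_bwd(d, fw$pre[[i]])
    g <- dense_bwd(d, fw$acts[[i]], layers[[i]])
    grads[[i]] <- list(W = g$dW, b = g$db)
    d <- g$dx
  }
  grads
}

#' Encode a metadata vector as a token sequence
#'
#' Passes the encoded clinical record through the metadata MLP and reshapes
#' the output to `n_tokens x d_model` (token-major).
#'
#' @param model An [mmf_model()] (or fitted [mmf_net()]).
#' @param meta Numeric vector of length `model$meta_width` (see
#'   [encode_record()]).
#' @return `n_tokens x d_model` token matrix.
#' @export
encode_meta <- function(model, meta) {
  if (!model$config$use_meta) stop("metadata branch is disabled in this config")
  if (length(meta) != model$meta_width) {
    stop("metadata vector length mismatch: expected ", model$meta_width,
         ", got ", length(meta))
  }
  stopifnot_finite(meta, "meta")
  encode_meta_fwd(as.numeric(meta), model$params, model$config)
}

# --- attention blocks with optional residual + layer norm -------------------

block_fwd <- function(x_qv, x_k, block, n_heads, ln) {
  ap <- as_attention_params(block, n_heads)
  mc <- mha_fwd(x_qv, x_k, ap, cache = TRUE)
  if (ln) {
    pre <- x_qv + mc$out
    list(out = layer_norm(pre), mc = mc, pre = pre, ap = ap)
  } else {
    list(out = mc$out, mc = mc, pre = NULL, ap = ap)
  }
}

block_bwd <- function(dout, cache, ln) {
  dres <- NULL
  if (ln) {
    dout <- layer_norm_bwd(dout, cache$pre)
    dres <- dout # residual path
  }
  g <- mha_bwd(dout, cache$mc, cache$ap)
  if (ln) g$dx_qv <- g$dx_qv + dres
  list(dW = list(W_q = g$dW_q, W_k = g$dW_k, W_v = g$dW_v),
       dx_qv = g$dx_qv, dx_k = g$dx_k)
}

# --- fusion -----------------------------------------------------------------

fuse_fwd <- function(xi, xm, params, config, cache = FALSE) {
  ln <- config$use_residual_layernorm
  nh <- config$n_heads
  cc <- list()
  if (config$use_self_attention) {
    cc$si <- block_fwd(xi, xi, params$self_img, nh, ln)
    xi1 <- cc$si$out
    if (config$use_meta) {
      cc$sm <- block_fwd(xm, xm, params$self_meta, nh, ln)
      xm1 <- cc$sm$out
    } else xm1 <- NULL
  } else {
    xi1 <- xi; xm1 <- xm
  }
  if (config$use_meta && config$use_cross_attention) {
    cc$ci <- block_fwd(xi1, xm1, params$cross_img, nh, ln)
    cc$cm <- block_fwd(xm1, xi1, params$cross_meta, nh, ln)
    xi2 <- cc$ci$out; xm2 <- cc$cm$out
  } else {
    xi2 <- xi1; xm2 <- xm1
  }
  x_final <- if (config$use_meta) {
    c(flatten_tokens(xm2), flatten_tokens(xi2))
  } else {
    flatten_tokens(xi2)
  }
  if (!cache) return(x_final)
  list(x_final = x_final, cc = cc, xi = xi, xm = xm)
}

fuse_bwd <- function(dx_final, fw, params, config) {
  L <- config$n_tokens; d <- config$d_model
  ln <- config$use_residual_layernorm
  unflatten <- function(v) matrix(v, nrow = L, byrow = TRUE)
  grads <- list()
  if (config$use_meta) {
    dxm2 <- unflatten(dx_final[seq_len(L * d)])
    dxi2 <- unflatten(dx_final[L * d + seq_len(L * d)])
  } else {
    dxm2 <- NULL
    dxi2 <- unflatten(dx_final)
  }
  if (config$use_meta && config$use_cross_attention) {
    gi <- block_bwd(dxi2, fw$cc$ci, ln)
    gm <- block_bwd(dxm2, fw$cc$cm, ln)
    grads$cross_img <- gi$dW
    grads$cross_meta <- gm$dW
    dxi1 <- gi$dx_qv + gm$dx_k
    dxm1 <- gm$dx_qv + gi$dx_k
  } else {
    dxi1 <- dxi2; dxm1 <- dxm2
  }
  if (config$use_self_attention) {
    gi <- block_bwd(dxi1, fw$cc$si, ln)
    grads$self_img <- gi$dW
    dxi <- gi$dx_qv + gi$dx_k
    if (config$use_meta) {
      gm <- block_bwd(dxm1, fw$cc$sm, ln)
      grads$self_meta <- gm$dW
      dxm <- gm$dx_qv + gm$dx_k
    } else dxm <- NULL
  } else {
    dxi <- dxi1; dxm <- dxm1
  }
  list(grads = grads, dxi = dxi, dxm = dxm)
}

#' Fuse image and metadata token sequences
#'
#' Applies the configured fusion pipeline: optional intra-modality
#' self-attention on each modality, optional bidirectional inter-modality
#' cross-attention (image tokens provide Query/Value with metadata Keys on
#' one path and vice versa on the other), then flattens and concatenates
#' the metadata tokens followed by the image tokens. With both stages
#' switched off this is the plain concatenation baseline.
#'
#' @param model An [mmf_model()].
#' @param x_img Image token sequence from [encode_image()].
#' @param x_meta Metadata token sequence from [encode_meta()] (`NULL` when
#'   the metadata branch is disabled).
#' @return Numeric fused feature vector of length
#'   `2 * n_tokens * d_model` (or half that without the metadata branch).
#' @export
fuse <- function(model, x_img, x_meta = NULL) {
  if (model$config$use_meta && is.null(x_meta)) {
    stop("x_meta is required when the metadata branch is enabled")
  }
  fuse_fwd(x_img, x_meta, model$params, model$config)
}

#' Classify a fused feature vector
#'
#' Single affine map to six logits followed by a max-subtraction softmax.
#'
#' @param model An [mmf_model()].
#' @param x_final Fused feature vector from [fuse()].
#' @return Named length-6 probability vector over [lesion_classes()],
#'   summing to 1.
#' @export
classify <- function(model, x_final) {
  if (length(x_final) != nrow(model$params$cls$W)) {
    stop("fused feature length mismatch: expected ", nrow(model$params$cls$W),
         ", got ", length(x_final))
  }
  logits <- dense_fwd(matrix(x_final, nrow = 1L), model$params$cls)
  stats::setNames(softmax_vec(as.numeric(logits)), lesion_classes())
}

# Full cached forward for one sample (training path).
forward_sample <- function(params, arch, config, x_img_vec, meta_vec) {
  fi <- encode_image_fwd(x_img_vec, params, arch, config, cache = TRUE)
  fm <- if (config$use_meta) {
    encode_meta_fwd(meta_vec, params, config, cache = TRUE)
  } else NULL
  ff <- fuse_fwd(fi$tokens, if (is.null(fm)) NULL else fm$tokens,
                 params, config, cache = TRUE)
  logits <- as.numeric(dense_fwd(matrix(ff$x_final, nrow = 1L), params$cls))
  probs <- softmax_vec(logits)
  list(probs = probs, logits = logits, fi = fi, fm = fm, ff = ff)
}

# Backward for one sample given d(logits); returns a gradient tree shaped
# like the trainable parameter tree.
backward_sample <- function(dlogits, fw, params, arch, config) {
  g_cls <- dense_bwd(matrix(dlogits, nrow = 1L),
                     matrix(fw$ff$x_final, nrow = 1L), params$cls)
  fb <- fuse_bwd(as.numeric(g_cls$dx), fw$ff, params, config)
  grads <- fb$grads
  grads$cls <- list(W = g_cls$dW, b = g_cls$db)
  grads$img <- encode_image_bwd(fb$dxi, fw$fi, params, arch)
  if (config$use_meta) grads$meta <- encode_meta_bwd(fb$dxm, fw$fm, params)
  grads[names(params)] # align order with params tree
}

#' Forward pass: class probabilities for one or more samples
#'
#' Computes `p(y = c | image, metadata)` for the six lesion classes.
#' Inference is deterministic (no augmentation or dropout).
#'
#' @param model An [mmf_model()] or fitted [mmf_net()].
#' @param images One image array or a list of image arrays.
#' @param meta Encoded metadata vector, or a matrix with one row per image
#'   (ignored when the metadata branch is disabled).
#' @return `n x 6` matrix of class probabilities; each row sums to 1.
#' @export
mmf_forward <- function(model, images, meta = NULL) {
  if (!is.list(images)) images <- list(images)
  n <- length(images)
  if (model$config$use_meta) {
    if (is.null(meta)) stop("meta is required when the metadata branch is enabled")
    if (is.null(dim(meta))) meta <- matrix(meta, nrow = 1L)
    if (nrow(meta) != n) stop("meta must have one row per image")
    if (ncol(meta) != model$meta_width) {
      stop("metadata width mismatch: expected ", model$meta_width,
           ", got ", ncol(meta))
    }
  }
  out <- matrix(0, n, 6L, dimnames = list(NULL, lesion_classes()))
  for (i in seq_len(n)) {
    x <- image_to_vec(images[[i]], model$config)
    fw <- forward_sample(model$params, model$arch, model$config, x,
                         if (model$config$use_meta) as.numeric(meta[i, ]) else NULL)
    out[i, ] <- fw$probs
  }
  out
}

#' Trainable parameter group names of a model
#'
#' Useful for ablation checks: switching off self- or cross-attention
#' removes exactly those projection groups from the trainable set.
#'
#' @param model An [mmf_model()].
#' @return Character vector of top-level parameter group names.
#' @export
parameter_groups <- function(model) names(model$params)

#' @export
print.mmf_model <- function(x, ...) {
  cfg <- x$config
  n_par <- length(tree_unlist(x$params))
  cat("Multimodal fusion model (", cfg$backbone, " backbone)\n", sep = "")
  cat("  tokens: ", cfg$n_tokens, " x ", cfg$d_model, ", heads: ", cfg$n_heads,
      "\n", sep = "")
  cat("  self-attention:", cfg$use_self_attention,
      "| cross-attention:", cfg$use_cross_attention,
      "| metadata branch:", cfg$use_meta, "\n")
  cat("  trainable parameters:", n_par, "| init seed:", cfg$seed, "\n")
  invisible(x)
}
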