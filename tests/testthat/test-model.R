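# Fusion model contracts: encoder shapes, determinism, fusion pipeline,
# classifier, ablation parameter groups, and analytic-vs-numerical
# gradients of the full backward pass.

test_that("encoders emit the configured token shapes deterministically", {
  cfg <- tiny_config(seed = 3L)
  sch <- build_default_schema()
  m <- mmf_model(cfg, meta_width = sch$width)
  img <- random_image(16, seed = 1)
  ti <- encode_image(m, img)
  expect_identical(dim(ti), c(2L, 8L))
  expect_identical(encode_image(m, img), ti) # evaluation-mode determinism
  meta <- encode_record(sch, list(age = 0.4, gender = "male", bleed = TRUE))
  tm <- encode_meta(m, meta)
  expect_identical(dim(tm), c(2L, 8L))
  expect_identical(encode_meta(m, meta), tm)
  expect_error(encode_meta(m, c(meta, 0)), "expected 58, got 59")
  expect_error(encode_image(m, array(0, c(8, 8, 3))), "16x16")
  expect_error(encode_image(m, img[, , 1:2]), "H x W x 3")
})

test_that("an all-zero image with zero biases yields all-zero tokens", {
  cfg <- tiny_config(seed = 4L, img_mean = 0, img_sd = 1)
  m <- mmf_model(cfg, meta_width = 10)
  m$params$img$conv1$b[] <- 0
  m$params$img$conv2$b[] <- 0
  m$params$img$proj$b[] <- 0
  tokens <- encode_image(m, array(0, c(16, 16, 3)))
  expect_true(all(tokens == 0))
})

test_that("fuse concatenates meta then image tokens; flags reduce it to plain concat", {
  cfg <- tiny_config(seed = 5L)
  sch <- build_default_schema()
  m <- mmf_model(cfg, meta_width = sch$width)
  img <- random_image(16, seed = 2)
  meta <- encode_record(sch, list(age = 1, itch = TRUE))
  ti <- encode_image(m, img); tm <- encode_meta(m, meta)
  xf <- fuse(m, ti, tm)
  expect_length(xf, 2L * cfg$n_tokens * cfg$d_model)
  # both attention stages off -> flatten-and-concatenate of encoder outputs
  ccfg <- variant_config(cfg, "concat")
  mc <- mmf_model(ccfg, meta_width = sch$width)
  mc$params$img <- m$params$img
  mc$params$meta <- m$params$meta
  xf0 <- fuse(mc, ti, tm)
  expect_equal(xf0, c(as.vector(t(tm)), as.vector(t(ti))), tolerance = 1e-12)
})

test_that("with identity-like projections at L = 1, fuse reduces to projected concat", {
  sch <- build_default_schema()
  cfg <- fusion_config(d_model = 8L, n_tokens = 1L, n_heads = 1L,
                       image_size = 16L, meta_hidden_sizes = 8L, seed = 6L)
  m <- mmf_model(cfg, meta_width = sch$width)
  eye <- diag(8)
  for (blk in c("self_img", "self_meta", "cross_img", "cross_meta")) {
    m$params[[blk]]$W_q <- eye; m$params[[blk]]$W_k <- eye; m$params[[blk]]$W_v <- eye
  }
  img <- random_image(16, seed = 3)
  meta <- encode_record(sch, list(age = 0.7))
  ti <- encode_image(m, img); tm <- encode_meta(m, meta)
  # L = 1: every attention stage is the identity V-projection, here exactly V
  expect_equal(fuse(m, ti, tm), c(as.vector(tm), as.vector(ti)),
               tolerance = 1e-10)
})

test_that("classifier returns stable six-class probabilities", {
  cfg <- tiny_config(seed = 7L)
  m <- mmf_model(cfg, meta_width = 10)
  d_in <- nrow(m$params$cls$W)
  # zero weights -> uniform distribution
  m0 <- m; m0$params$cls$W[] <- 0; m0$params$cls$b[] <- 0
  expect_equal(unname(classify(m0, rnorm(d_in))), rep(1 / 6, 6))
  # huge logits survive via max-subtraction softmax
  m1 <- m0; m1$params$cls$b <- c(1000, 0, 0, 0, 0, 0)
  p <- classify(m1, numeric(d_in))
  expect_false(any(is.nan(p)))
  expect_equal(unname(p), c(1, 0, 0, 0, 0, 0))
  expect_error(classify(m, numeric(3)), "length mismatch")
})

test_that("forward produces per-sample probability rows and is reproducible", {
  cfg <- tiny_config(seed = 8L)
  sch <- build_default_schema()
  m <- mmf_model(cfg, meta_width = sch$width)
  imgs <- lapply(1:3, function(i) random_image(16, seed = i))
  meta <- encode_table(sch, list(list(age = 1), list(itch = TRUE), list()))
  pr <- mmf_forward(m, imgs, meta)
  expect_identical(dim(pr), c(3L, 6L))
  expect_equal(unname(rowSums(pr)), rep(1, 3), tolerance = 1e-9)
  m2 <- mmf_model(cfg, meta_width = sch$width) # same seed -> same params
  expect_identical(mmf_forward(m2, imgs, meta), pr)
})

test_that("ablation switches remove exactly the matching parameter groups", {
  sch <- build_default_schema()
  base <- tiny_config(seed = 9L)
  groups <- function(v) {
    parameter_groups(mmf_model(variant_config(base, v), meta_width = sch$width))
  }
  expect_setequal(groups("full"), c("img", "meta", "self_img", "self_meta",
                                    "cross_img", "cross_meta", "cls"))
  expect_setequal(setdiff(groups("full"), groups("no_self")),
                  c("self_img", "self_meta"))
  expect_setequal(setdiff(groups("full"), groups("no_cross")),
                  c("cross_img", "cross_meta"))
  expect_setequal(groups("concat"), c("img", "meta", "cls"))
  expect_setequal(groups("image_only"), c("img", "cls"))
})

test_that("analytic gradients match central differences on every group", {
  sch <- build_default_schema()
  for (setup in list(list(cfg = tiny_config(seed = 10L), label = "default"),
                     list(cfg = tiny_config(seed = 11L,
                                            use_residual_layernorm = TRUE),
                          label = "residual+layernorm"))) {
    cfg <- setup$cfg
    m <- mmf_model(cfg, meta_width = sch$width)
    img <- random_image(16, seed = 20)
    meta <- encode_record(sch, list(age = 0.8, gender = "female", grew = TRUE))
    x <- mmfuse:::image_to_vec(img, cfg)
    loss_fn <- function(params) {
      fw <- mmfuse:::forward_sample(params, m$arch, cfg, x, as.numeric(meta))
      -log(fw$probs[4])
    }
    fw <- mmfuse:::forward_sample(m$params, m$arch, cfg, x, as.numeric(meta))
    dlogits <- fw$probs - as.numeric(seq_len(6) == 4)
    g <- mmfuse:::backward_sample(dlogits, fw, m$params, m$arch, cfg)
    expect_true(all(is.finite(tree_unlist(g)))) # finite loss -> finite grads
    eps <- 1e-6
    paths <- list(c("img", "conv1", "W"), c("img", "conv2", "b"),
                  c("img", "proj", "W"), c("meta", "1", "W"),
                  c("meta", "2", "b"), c("self_img", "W_q"),
                  c("self_meta", "W_v"), c("cross_img", "W_k"),
                  c("cross_meta", "W_q"), c("cls", "W"))
    for (pth in paths) {
      pth <- as.list(pth)
      leaf <- m$params; gl <- g
      for (k in pth) {
        k <- if (grepl("^[0-9]+$", k)) as.integer(k) else k
        leaf <- leaf[[k]]; gl <- gl[[k]]
      }
      ii <- withr::with_seed(1, sample(length(leaf), min(3, length(leaf))))
      for (i in ii) {
        bump <- function(delta) {
          p2 <- m$params
          ref <- function(t, path, d) {
            k <- path[[1]]
            k <- if (grepl("^[0-9]+$", k)) as.integer(k) else k
            if (length(path) == 1L) { t[[k]][i] <- t[[k]][i] + d; t }
            else { t[[k]] <- ref(t[[k]], path[-1], d); t }
          }
          ref(p2, pth, delta)
        }
        num <- (loss_fn(bump(eps)) - loss_fn(bump(-eps))) / (2 * eps)
        expect_lt(abs(num - gl[i]), 1e-6,
                  label = paste(setup$label, paste(unlist(pth), collapse = "/"),
                                "grad err"))
      }
    }
  }
})

test_that("checkpoints and YAML configs round-trip", {
  cfg <- tiny_config(seed = 12L, normalize_meta = TRUE)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_config(cfg, f)
  expect_equal(read_config(f), cfg)
  ds <- generate_dataset(synth_spec(n_per_class = rep(2L, 6L),
                                    image_size = 16L, seed = 12))
  ctl <- train_control(epochs = 2, lr0 = 0.02, seed = 12)
  fit <- mmf_net(ds$images, ds$labels, ds$records, cfg, ctl,
                 build_default_schema())
  ckpt <- withr::local_tempfile(fileext = ".rds")
  write_checkpoint(fit, ckpt)
  back <- read_checkpoint(ckpt)
  expect_identical(predict(back, ds$images[1:2], ds$records[1:2]),
                   predict(fit, ds$images[1:2], ds$records[1:2]))
  expect_identical(back$schema$width, fit$schema$width)
})

test_that("the resnet50 backbone is declared but rejected as out of scope", {
  cfg <- fusion_config(backbone = "resnet50")
  expect_error(mmf_model(cfg, meta_width = 10), "resnet50")
})
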