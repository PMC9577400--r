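# Training harness: stratified folds, plateau schedule, augmentation,
# descent on separable data, and fold evaluation contracts.

test_that("stratified 5-fold split partitions with per-class counts within 1", {
  labels <- rep(lesion_classes(), pad_ufes_proportions(300))
  folds <- suppressWarnings(stratified_kfold(labels, k = 5, seed = 2))
  all_idx <- sort(unlist(folds))
  expect_identical(all_idx, seq_along(labels)) # partition, no overlap
  for (cls in lesion_classes()) {
    per_fold <- vapply(folds, function(f) sum(labels[f] == cls), integer(1))
    expect_lte(max(per_fold) - min(per_fold), 1L)
  }
  # balanced 2-class example splits exactly
  lab2 <- rep(c("ACK", "BCC"), each = 50)
  f2 <- stratified_kfold(lab2, k = 5, seed = 3)
  expect_true(all(vapply(f2, function(f) sum(lab2[f] == "ACK"), integer(1)) == 10))
  # determinism
  expect_identical(stratified_kfold(labels, 5, seed = 9)[[1]],
                   suppressWarnings(stratified_kfold(labels, 5, seed = 9)[[1]]))
  expect_error(stratified_kfold(1:3, k = 5), "exceed")
})

test_that("dataset-proportioned MEL counts per fold are 10 or 11", {
  labels <- rep(lesion_classes(), pad_ufes_proportions())
  folds <- stratified_kfold(labels, k = 5, seed = 4)
  mel <- vapply(folds, function(f) sum(labels[f] == "MEL"), integer(1))
  expect_true(all(mel %in% c(10L, 11L))) # 52 MEL over 5 folds
  expect_equal(sum(mel), 52L)
})

test_that("plateau schedule drops lr exactly x0.1 after 10 flat epochs", {
  # scripted losses: one improvement, then flat -> drop at epoch 12's rate
  ctl <- train_control(epochs = 100, lr0 = 0.001, plateau_patience = 10)
  losses <- c(1, rep(1, 99)) # flat after the initial best
  tr <- run_schedule(function(e, lr) losses[e], ctl)
  expect_length(tr$loss, 100L) # exactly 100 epochs, no early stop
  expect_length(tr$lr, 100L)
  expect_equal(tr$lr[11], 0.001) # epoch 11 still trains at lr0 ...
  expect_equal(tr$lr[12], 0.0001) # ... and the drop shows from epoch 12
  expect_true(all(diff(tr$lr) <= 0)) # non-increasing
  drops <- diff(tr$lr)[diff(tr$lr) < 0]
  ratio <- tr$lr[which(diff(tr$lr) < 0) + 1] / tr$lr[which(diff(tr$lr) < 0)]
  expect_equal(ratio, rep(0.1, length(ratio)), tolerance = 1e-12)
  expect_gte(min(tr$lr), 1e-6) # floor
  # an improving sequence never drops
  tr2 <- run_schedule(function(e, lr) 1 - e * 0.01,
                      train_control(epochs = 50))
  expect_equal(unique(tr2$lr), 0.001)
  # non-finite loss aborts with a diagnostic
  expect_error(run_schedule(function(e, lr) NaN, train_control(epochs = 5)),
               "non-finite")
})

test_that("plateau scheduler honors the improvement tolerance", {
  sch <- plateau_scheduler(0.1, factor = 0.1, patience = 3, tol = 1e-4)
  sch$step(1)
  # improvements below tol do not reset patience
  sch$step(1 - 1e-5); sch$step(1 - 2e-5)
  expect_equal(sch$step(1 - 3e-5), 0.01)
})

test_that("augmentation is seeded, range-preserving, and off-switchable", {
  img <- random_image(16, seed = 5)
  ctl <- train_control()
  a1 <- withr::with_seed(11, augment_image(img, ctl))
  a2 <- withr::with_seed(11, augment_image(img, ctl))
  expect_identical(a1, a2)
  expect_true(all(a1 >= 0 & a1 <= 1))
  expect_false(identical(a1, img))
  off <- train_control(augment = FALSE)
  expect_identical(augment_image(img, off), img)
  # flips are involutions
  expect_identical(mmfuse:::flip_h(mmfuse:::flip_h(img)), img)
  expect_identical(mmfuse:::flip_v(mmfuse:::flip_v(img)), img)
})

test_that("training loss descends on separable synthetic data", {
  ds <- generate_dataset(synth_spec(n_per_class = rep(10L, 6L),
                                    image_size = 16L, alpha = 0, beta = 1,
                                    missing_rate = 0, seed = 31))
  sch <- build_default_schema()
  cfg <- tiny_config(seed = 31L, normalize_meta = TRUE)
  ctl <- train_control(epochs = 20, batch_size = 16, lr0 = 0.05, seed = 31)
  fit <- mmf_net(ds$images, ds$labels, ds$records, cfg, ctl, sch)
  expect_length(fit$trace$loss, 20L)
  expect_lt(fit$trace$loss[20], fit$trace$loss[1])
  # a memorizing model (no augmentation noise, a little more capacity)
  # scores near-perfectly on its own training set
  cfg_mem <- fusion_config(d_model = 16L, n_tokens = 2L, n_heads = 2L,
                           image_size = 16L, meta_hidden_sizes = 16L,
                           seed = 31L, normalize_meta = TRUE)
  ctl_mem <- train_control(epochs = 40, batch_size = 16, lr0 = 0.05,
                           seed = 31, augment = FALSE)
  fit_mem <- mmf_net(ds$images, ds$labels, ds$records, cfg_mem, ctl_mem, sch)
  train_rep <- evaluate_fold(fit_mem, ds, seq_along(ds$labels))
  expect_gt(train_rep$acc, 0.9)
  # determinism end to end: same seeds -> identical refit and reports
  fit2 <- mmf_net(ds$images, ds$labels, ds$records, cfg, ctl, sch)
  expect_identical(fit$trace$loss, fit2$trace$loss)
  expect_identical(predict(fit, ds$images[1:2], ds$records[1:2]),
                   predict(fit2, ds$images[1:2], ds$records[1:2]))
})

test_that("evaluate_fold is deterministic and rejects train/test overlap", {
  ds <- generate_dataset(synth_spec(n_per_class = rep(4L, 6L),
                                    image_size = 16L, seed = 32))
  sch <- build_default_schema()
  cfg <- tiny_config(seed = 32L)
  ctl <- train_control(epochs = 2, lr0 = 0.01, seed = 32)
  # interleaved split so both halves contain every class
  idx <- which(seq_len(24L) %% 2L == 1L)
  fit <- train_fold(ds, idx, cfg, ctl, sch)
  test_idx <- which(seq_len(24L) %% 2L == 0L)
  r1 <- evaluate_fold(fit, ds, test_idx, idx)
  r2 <- evaluate_fold(fit, ds, test_idx, idx)
  expect_identical(r1$acc, r2$acc)
  expect_identical(r1$confusion, r2$confusion)
  expect_true(all(c(r1$acc, r1$bacc, r1$auc) >= 0 &
                    c(r1$acc, r1$bacc, r1$auc) <= 1))
  expect_error(evaluate_fold(fit, ds, c(1L, 14L), idx), "overlap")
})

test_that("run_cv produces paired per-fold reports and a consistent summary", {
  ds <- generate_dataset(synth_spec(n_per_class = rep(6L, 6L),
                                    image_size = 16L, alpha = 0, beta = 1,
                                    missing_rate = 0, seed = 33))
  cfg <- tiny_config(seed = 33L, normalize_meta = TRUE)
  ctl <- train_control(epochs = 3, lr0 = 0.05, seed = 33)
  cv <- run_cv(ds, cfg, ctl, k = 3, variants = c("concat", "full"), seed = 33)
  expect_length(cv$variants$full$reports, 3L)
  expect_length(cv$variants$concat$reports, 3L)
  resum <- summarize_folds(cv$variants$full$reports)
  expect_identical(cv$variants$full$summary, resum)
  # both variants share the fold split (paired comparisons)
  expect_identical(cv$folds, stratified_kfold(ds$labels, 3, seed = 33))
  fm <- cv_fold_metrics(cv, "bacc")
  expect_named(fm, c("concat", "full"))
  expect_length(fm$full, 3L)
})
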