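# Cross-validation harness: stratified k-fold splits, on-the-fly image
# augmentation, per-fold training/evaluation, and multi-variant runs sharing
# one fold split (so method comparisons are fold-paired).

#' Stratified k-fold split
#'
#' Partitions sample indices into `k` test folds so that each class's
#' members are spread across folds as evenly as possible (per-class fold
#' counts differ by at most one). Deterministic given `seed`. Classes with
#' fewer than `k` members trigger a warning (some folds then lack them).
#'
#' @param labels Class labels.
#' @param k Number of folds.
#' @param seed RNG seed for the within-class shuffle.
#' @return Object of class `fold_split`: list of `k` integer vectors of
#'   test indices, with the labels attached.
#' @export
stratified_kfold <- function(labels, k = 5L, seed = 1L) {
  n <- length(labels)
  if (k > n) stop("k must not exceed the number of samples")
  y <- as.character(labels)
  folds <- vector("list", k)
  withr::with_seed(seed, {
    for (cls in sort(unique(y))) {
      idx <- which(y == cls)
      if (length(idx) < k) {
        warning("class ", cls, " has fewer than k = ", k, " members")
      }
      idx <- idx[sample.int(length(idx))]
      assign_to <- rep(seq_len(k), length.out = length(idx))
      for (f in seq_len(k)) {
        folds[[f]] <- c(folds[[f]], idx[assign_to == f])
      }
    }
  })
  folds <- lapply(folds, sort)
  structure(folds, class = "fold_split", labels = labels)
}

#' @export
print.fold_split <- function(x, ...) {
  cat("Stratified", length(x), "fold split of", length(attr(x, "labels")),
      "samples\n")
  for (f in seq_along(x)) {
    cat("  fold", f, ":", length(x[[f]]), "test samples\n")
  }
  invisible(x)
}

flip_h <- function(image) image[, rev(seq_len(dim(image)[2])), , drop = FALSE]
flip_v <- function(image) image[rev(seq_len(dim(image)[1])), , , drop = FALSE]

#' Stochastic training-time image augmentation
#'
#' Composes horizontal and vertical flips, color jitter (per-channel
#' brightness and saturation shifts), additive Gaussian noise and random
#' contrast scaling, with magnitudes from the [train_control()]. Draws from
#' the current RNG stream; the pixel range `[0, 1]` is preserved by
#' clipping. With `control$augment = FALSE` the image is returned
#' unchanged.
#'
#' @param image `H x W x 3` array in `[0, 1]`.
#' @param control A [train_control()].
#' @return Augmented image array of the same shape.
#' @export
augment_image <- function(image, control = train_control()) {
  if (!control$augment) return(image)
  if (stats::runif(1) < control$flip_p) image <- flip_h(image)
  if (stats::runif(1) < control$flip_p) image <- flip_v(image)
  # color jitter: global brightness shift plus a saturation-like per-channel
  # shift around the pixel's gray value
  if (control$jitter > 0) {
    image <- image + stats::runif(1, -control$jitter, control$jitter)
    gray <- (image[, , 1] + image[, , 2] + image[, , 3]) / 3
    sat <- stats::runif(1, 1 - control$jitter, 1 + control$jitter)
    for (c in 1:3) image[, , c] <- gray + sat * (image[, , c] - gray)
  }
  if (control$noise_sd > 0) {
    image <- image + array(stats::rnorm(length(image), 0, control$noise_sd),
                           dim = dim(image))
  }
  f <- stats::runif(1, control$contrast_range[1], control$contrast_range[2])
  image <- (image - 0.5) * f + 0.5
  pmin(pmax(image, 0), 1)
}

#' Train the model on one training fold
#'
#' Thin wrapper around [mmf_net()] restricted to the given indices; the
#' fold's featurization (including any numeric standardization) is fitted
#' on the training indices only.
#'
#' @param dataset A dataset list with `images`, `records` (or encoded
#'   `meta`), `labels` (see [generate_dataset()] / [read_pad_ufes()]).
#' @param train_idx Integer indices of the training samples.
#' @param config A [fusion_config()].
#' @param control A [train_control()].
#' @param schema A [meta_schema()] (required with raw records).
#' @return A fitted [mmf_net()].
#' @export
train_fold <- function(dataset, train_idx, config, control,
                       schema = build_default_schema()) {
  stopifnot(length(train_idx) >= 1L)
  meta <- if (!config$use_meta) NULL
          else if (!is.null(dataset$meta)) dataset$meta[train_idx, , drop = FALSE]
          else dataset$records[train_idx]
  mmf_net(dataset$images[train_idx], dataset$labels[train_idx], meta,
          config = config, control = control, schema = schema)
}

#' Evaluate a trained model on a held-out fold
#'
#' Deterministic inference (no augmentation) on the test indices, which
#' must be disjoint from the training indices used to fit the model.
#'
#' @param fit A fitted [mmf_net()].
#' @param dataset The dataset the fold indices refer to.
#' @param test_idx Integer indices of the held-out samples.
#' @param train_idx Training indices, for the disjointness assertion.
#' @return A [metrics_report()] with the prediction set attached as
#'   attribute `"predictions"`.
#' @export
evaluate_fold <- function(fit, dataset, test_idx, train_idx = NULL) {
  if (!is.null(train_idx) && length(intersect(test_idx, train_idx))) {
    stop("test indices overlap the training set")
  }
  meta <- if (!fit$config$use_meta) NULL
          else if (!is.null(dataset$meta)) dataset$meta[test_idx, , drop = FALSE]
          else dataset$records[test_idx]
  probs <- predict(fit, dataset$images[test_idx], meta)
  p <- prediction_set(probs, dataset$labels[test_idx])
  rep <- metrics_report(p)
  attr(rep, "predictions") <- p
  rep
}

#' Cross-validated evaluation of model variants
#'
#' Runs stratified `k`-fold cross-validation: for each fold and each
#' requested variant an independent model is trained on the fold's training
#' set and evaluated on the held-out fold. All variants share the same fold
#' split, so per-fold metrics are paired across variants (as required by
#' fold-paired significance tests, see [compare_methods()]).
#'
#' @param dataset Dataset list with `images`, `records`/`meta`, `labels`.
#' @param config Base [fusion_config()].
#' @param control A [train_control()].
#' @param k Number of folds.
#' @param variants Character vector of [variant_config()] names.
#' @param seed Seed for the fold split and per-fold model/train seeds.
#' @param schema A [meta_schema()] (with raw records).
#' @param folds Optional pre-built [stratified_kfold()] split to reuse.
#' @return Object of class `mmf_cv`: per-variant lists of
#'   [metrics_report()]s, fold summaries, the fold split and fitted-model
#'   traces.
#' @export
run_cv <- function(dataset, config = fusion_config(), control = train_control(),
                   k = 5L, variants = "full", seed = 1L,
                   schema = build_default_schema(), folds = NULL) {
  n <- length(dataset$images)
  stopifnot(n >= k)
  if (is.null(folds)) folds <- stratified_kfold(dataset$labels, k, seed)
  out <- list()
  for (v in variants) {
    vcfg <- variant_config(config, v)
    reports <- vector("list", length(folds))
    traces <- vector("list", length(folds))
    for (f in seq_along(folds)) {
      test_idx <- folds[[f]]
      train_idx <- setdiff(seq_len(n), test_idx)
      vcfg$seed <- seed * 1000L + f
      fctl <- control
      fctl$seed <- seed * 1000L + f
      fit <- train_fold(dataset, train_idx, vcfg, fctl, schema)
      reports[[f]] <- evaluate_fold(fit, dataset, test_idx, train_idx)
      traces[[f]] <- fit$trace
    }
    out[[v]] <- list(reports = reports, summary = summarize_folds(reports),
                     traces = traces)
  }
  structure(list(variants = out, folds = folds, config = config,
                 control = control, seed = seed), class = "mmf_cv")
}

#' @export
print.mmf_cv <- function(x, ...) {
  cat("Cross-validated evaluation (", length(x$folds), " folds)\n", sep = "")
  for (v in names(x$variants)) {
    s <- x$variants[[v]]$summary
    cat(sprintf("  %-11s ACC %s  BACC %s  AUC %s\n", v,
                s$formatted[s$metric == "acc"],
                s$formatted[s$metric == "bacc"],
                s$formatted[s$metric == "auc"]))
  }
  invisible(x)
}

#' Per-fold metric vectors of a cross-validation run
#'
#' @param cv An [run_cv()] result.
#' @param metric One of `"acc"`, `"bacc"`, `"auc"`.
#' @return Named list of per-variant numeric fold vectors (fold-paired).
#' @export
cv_fold_metrics <- function(cv, metric = c("bacc", "acc", "auc")) {
  metric <- match.arg(metric)
  lapply(cv$variants, function(v) {
    vapply(v$reports, function(r) r[[metric]], numeric(1))
  })
}
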