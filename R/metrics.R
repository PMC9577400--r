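# Evaluation metrics: accuracy, balanced accuracy (macro recall),
# aggregated pairwise multiclass AUC (Hand & Till), per-class one-vs-rest
# ROC curves, confusion matrix and fold aggregation.

#' Bundle predicted probabilities with true labels
#'
#' @param probs `n x 6` matrix of class probabilities (rows sum to 1).
#' @param labels True labels (factor/character over [lesion_classes()] or
#'   1-based integers).
#' @return An object of class `prediction_set`.
#' @export
prediction_set <- function(probs, labels) {
  probs <- as.matrix(probs)
  if (nrow(probs) < 1L) stop("prediction set must contain at least one sample")
  if (ncol(probs) != 6L) stop("probs must have 6 columns")
  stopifnot_finite(probs, "probs")
  if (any(abs(rowSums(probs) - 1) > 1e-6)) {
    stop("probability rows must sum to 1")
  }
  y <- as_lesion_factor(labels)
  if (length(y) != nrow(probs)) stop("labels length must match probs rows")
  colnames(probs) <- lesion_classes()
  structure(list(probs = probs, labels = y), class = "prediction_set")
}

# Argmax with ties broken toward the lowest class index (deterministic).
pred_classes <- function(p) apply(p$probs, 1, which.max)

#' Classification accuracy
#'
#' Fraction of samples whose highest-probability class equals the true
#' label; argmax ties break toward the lowest class index.
#'
#' @param p A [prediction_set()].
#' @return Accuracy in `[0, 1]`.
#' @export
accuracy <- function(p) {
  stopifnot(inherits(p, "prediction_set"))
  mean(pred_classes(p) == as.integer(p$labels))
}

#' Balanced accuracy (macro recall)
#'
#' Unweighted mean of per-class recall over the classes present in the
#' labels; absent classes are excluded from the mean. With two classes this
#' reduces to the arithmetic mean of sensitivity and specificity.
#'
#' @param p A [prediction_set()].
#' @return Balanced accuracy in `[0, 1]`.
#' @export
balanced_accuracy <- function(p) {
  stopifnot(inherits(p, "prediction_set"))
  yhat <- pred_classes(p)
  y <- as.integer(p$labels)
  present <- sort(unique(y))
  recalls <- vapply(present, function(c) mean(yhat[y == c] == c), numeric(1))
  mean(recalls)
}

# Pairwise AUC A(i|j): probability that a random class-i sample receives a
# higher p_i score than a random class-j sample (ties count 1/2), via the
# rank-sum formula.
pairwise_auc <- function(scores_i, scores_j) {
  n_i <- length(scores_i); n_j <- length(scores_j)
  r <- rank(c(scores_i, scores_j))
  (sum(r[seq_len(n_i)]) - n_i * (n_i + 1) / 2) / (n_i * n_j)
}

#' Aggregated pairwise multiclass AUC (Hand & Till)
#'
#' For every unordered class pair (i, j) with support in both classes,
#' restricts to the samples of those two classes, computes `A(i|j)` (the
#' probability that a random class-i sample scores higher on `p_i` than a
#' random class-j sample, ties counting one half) and its counterpart
#' `A(j|i)`, symmetrizes, and averages over all computable pairs (15 for
#' six classes). Pairs missing a class are skipped with a warning.
#'
#' @param p A [prediction_set()].
#' @return Aggregated AUC in `[0, 1]`.
#' @export
aggregated_auc <- function(p) {
  stopifnot(inherits(p, "prediction_set"))
  y <- as.integer(p$labels)
  present <- sort(unique(y))
  if (length(present) < 2L) stop("aggregated AUC needs >= 2 classes with support")
  pairs <- utils::combn(present, 2L)
  skipped <- ncol(utils::combn(6L, 2L)) - ncol(pairs)
  if (skipped > 0) {
    warning(skipped, " class pair(s) skipped for zero support")
  }
  vals <- apply(pairs, 2L, function(ij) {
    i <- ij[1]; j <- ij[2]
    si <- y == i; sj <- y == j
    a_ij <- pairwise_auc(p$probs[si, i], p$probs[sj, i])
    a_ji <- pairwise_auc(p$probs[sj, j], p$probs[si, j])
    (a_ij + a_ji) / 2
  })
  mean(vals)
}

#' Per-class one-vs-rest ROC curves and AUCs
#'
#' One curve per class with support, built from that class's probability
#' column against the binary class-membership indicator (via pROC); the
#' AUC equals the trapezoidal area under the empirical curve. Zero-support
#' classes are flagged and omitted.
#'
#' @param p A [prediction_set()].
#' @return Named list per class: `list(curve = data.frame(fpr, tpr),
#'   auc = <numeric>)`, or `NULL` for zero-support classes.
#' @export
per_class_roc <- function(p) {
  stopifnot(inherits(p, "prediction_set"))
  y <- as.integer(p$labels)
  out <- stats::setNames(vector("list", 6L), lesion_classes())
  for (c in seq_len(6L)) {
    if (!any(y == c) || all(y == c)) {
      warning("class ", lesion_classes()[c],
              " lacks positive or negative samples; ROC omitted")
      next
    }
    r <- pROC::roc(response = factor(y == c, levels = c(FALSE, TRUE)),
                   predictor = p$probs[, c], direction = "<", quiet = TRUE)
    curve <- data.frame(fpr = rev(1 - r$specificities),
                        tpr = rev(r$sensitivities))
    out[[c]] <- list(curve = curve, auc = as.numeric(r$auc))
  }
  out
}

#' Confusion matrix of argmax predictions
#'
#' @param p A [prediction_set()].
#' @param normalize Return row-normalized proportions instead of counts.
#' @return `6 x 6` matrix, rows = true class, columns = predicted class.
#' @export
confusion <- function(p, normalize = FALSE) {
  stopifnot(inherits(p, "prediction_set"))
  cls <- lesion_classes()
  m <- table(factor(cls[as.integer(p$labels)], levels = cls),
             factor(cls[pred_classes(p)], levels = cls))
  m <- unclass(as.matrix(m))
  names(dimnames(m)) <- c("true", "predicted")
  if (normalize) {
    rs <- rowSums(m)
    m <- m / ifelse(rs == 0, 1, rs)
  }
  m
}

#' Full metrics report for one evaluation
#'
#' @param p A [prediction_set()].
#' @return An object of class `metrics_report`: list with `acc`, `bacc`,
#'   `auc` (aggregated pairwise), `per_class_auc`, `confusion` and `n`.
#' @export
metrics_report <- function(p) {
  roc <- suppressWarnings(per_class_roc(p))
  structure(list(
    acc = accuracy(p),
    bacc = balanced_accuracy(p),
    auc = aggregated_auc(p),
    per_class_auc = vapply(roc, function(r) if (is.null(r)) NA_real_ else r$auc,
                           numeric(1)),
    confusion = confusion(p),
    roc = roc,
    n = nrow(p$probs)
  ), class = "metrics_report")
}

#' Write per-class ROC curves and the confusion matrix as CSV
#'
#' @param report A [metrics_report()].
#' @param roc_path,confusion_path Output files (`NULL` skips one).
#' @return `report`, invisibly.
#' @export
write_metrics_csv <- function(report, roc_path = NULL, confusion_path = NULL) {
  if (!is.null(roc_path)) {
    rows <- do.call(rbind, lapply(names(report$roc), function(cl) {
      r <- report$roc[[cl]]
      if (is.null(r)) return(NULL)
      cbind(class = cl, r$curve, auc = r$auc)
    }))
    utils::write.csv(rows, roc_path, row.names = FALSE)
  }
  if (!is.null(confusion_path)) {
    utils::write.csv(as.data.frame.matrix(report$confusion), confusion_path)
  }
  invisible(report)
}

#' Plot per-class ROC curves of a metrics report
#'
#' @param x A [metrics_report()].
#' @param ... Passed to [graphics::plot()].
#' @export
plot.metrics_report <- function(x, ...) {
  cols <- grDevices::hcl.colors(6, "Dark 3")
  graphics::plot(c(0, 1), c(0, 1), type = "l", lty = 3, col = "grey60",
                 xlab = "false positive rate", ylab = "true positive rate",
                 main = "One-vs-rest ROC per lesion class", ...)
  keep <- !vapply(x$roc, is.null, logical(1))
  for (i in which(keep)) {
    graphics::lines(x$roc[[i]]$curve$fpr, x$roc[[i]]$curve$tpr, col = cols[i])
  }
  graphics::legend("bottomright", bty = "n", col = cols[keep], lty = 1,
                   legend = sprintf("%s (AUC %.2f)", names(x$roc)[keep],
                                    x$per_class_auc[keep]))
  invisible(x)
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("ACC %.3f | BACC %.3f | aggregated AUC %.3f (n = %d)\n",
              x$acc, x$bacc, x$auc, x$n))
  invisible(x)
}

#' Aggregate per-fold metric reports as mean and SD
#'
#' Arithmetic mean and sample standard deviation per metric over folds,
#' with the conventional `"mean ± sd"` display at three decimals. A single
#' report yields SD 0 with a warning.
#'
#' @param reports List of [metrics_report()] objects.
#' @return Data frame with one row per metric (`acc`, `bacc`, `auc`):
#'   columns `mean`, `sd`, `formatted`.
#' @export
summarize_folds <- function(reports) {
  stopifnot(length(reports) >= 1L)
  if (length(reports) < 2L) {
    warning("fewer than 2 reports: SD reported as 0")
  }
  metrics <- c("acc", "bacc", "auc")
  rows <- lapply(metrics, function(m) {
    v <- vapply(reports, function(r) r[[m]], numeric(1))
    s <- if (length(v) >= 2L) stats::sd(v) else 0
    data.frame(metric = m, mean = mean(v), sd = s,
               formatted = sprintf("%.3f ± %.3f", mean(v), s))
  })
  do.call(rbind, rows)
}

#' Write a metrics report (or fold summary) as JSON
#'
#' @param report A [metrics_report()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_metrics_json <- function(report, path) {
  x <- unclass(report)
  x$confusion <- as.data.frame.matrix(x$confusion)
  x$roc <- NULL # curves go to CSV via write_metrics_csv()
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
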