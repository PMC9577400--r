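# Evaluation metrics against rank-count oracles and closed forms.

test_that("accuracy counts argmax hits with low-index tie-breaking", {
  probs <- rbind(c(0.9, 0.02, 0.02, 0.02, 0.02, 0.02),
                 c(0.02, 0.9, 0.02, 0.02, 0.02, 0.02),
                 c(0.02, 0.02, 0.9, 0.02, 0.02, 0.02),
                 c(0.9, 0.02, 0.02, 0.02, 0.02, 0.02))
  p <- prediction_set(probs, c(1, 2, 3, 2))
  expect_equal(accuracy(p), 0.75)
  expect_equal(accuracy(prediction_set(probs[1:3, ], 1:3)), 1)
  # uniform rows tie-break to class 1 (ACK)
  uni <- matrix(1 / 6, 4, 6)
  expect_equal(accuracy(prediction_set(uni, rep(1, 4))), 1)
  expect_equal(accuracy(prediction_set(uni, rep(2, 4))), 0)
})

test_that("balanced accuracy is macro recall, independent of class sizes", {
  # per-class recalls 1.0, 0.5, 0.0 with unequal supports -> 0.5
  onehot <- function(i) { v <- rep(0.01, 6); v[i] <- 0.95; v / sum(v) }
  probs <- rbind(onehot(1), onehot(1),            # class 1: 2/2 correct
                 onehot(2), onehot(3), onehot(2), onehot(3), # class 2: 2/4
                 onehot(1))                        # class 3: 0/1
  y <- c(1, 1, 2, 2, 2, 2, 3)
  p <- prediction_set(probs, y)
  expect_equal(balanced_accuracy(p), 0.5)
  # duplicating one class's samples leaves macro recall unchanged
  dup <- prediction_set(rbind(probs, probs[y == 2, ]), c(y, rep(2, 4)))
  expect_equal(balanced_accuracy(dup), 0.5)
  expect_lt(abs(accuracy(dup) - accuracy(p)), 0.2) # plain accuracy shifts
  # binary case: sensitivity 1, specificity 0.5 -> 0.75
  pb <- prediction_set(rbind(onehot(1), onehot(1), onehot(1), onehot(2)),
                       c(1, 1, 2, 2))
  expect_equal(balanced_accuracy(pb), 0.75)
})

test_that("aggregated pairwise AUC equals the exhaustive pair-count oracle", {
  # small sets may lack some classes; the skip warning is expected there
  p <- random_prediction_set(12, seed = 5)
  expect_equal(suppressWarnings(aggregated_auc(p)),
               brute_aggregated_auc(p$probs, p$labels), tolerance = 1e-12)
  for (seed in 6:10) {
    p <- random_prediction_set(30, seed = seed)
    expect_equal(suppressWarnings(aggregated_auc(p)),
                 brute_aggregated_auc(p$probs, p$labels), tolerance = 1e-12)
  }
})

test_that("aggregated AUC hits its closed-form extremes", {
  onehot <- function(i) { v <- rep(0.001, 6); v[i] <- 1 - 0.005; v / sum(v) }
  y <- rep(1:6, each = 2)
  perfect <- prediction_set(t(vapply(y, onehot, numeric(6))), y)
  expect_equal(aggregated_auc(perfect), 1)
  flat <- prediction_set(matrix(1 / 6, 12, 6), y)
  expect_equal(aggregated_auc(flat), 0.5) # all ties
  # invariant under strictly monotone transforms of the score columns
  p <- random_prediction_set(40, seed = 12)
  probs2 <- p$probs^3 # monotone, breaks row-normalization on purpose
  y2 <- as.integer(p$labels)
  expect_equal(mmfuse:::pairwise_auc(probs2[y2 == 1, 1], probs2[y2 == 2, 1]),
               mmfuse:::pairwise_auc(p$probs[y2 == 1, 1], p$probs[y2 == 2, 1]))
  # binary case (complementary scores): aggregated AUC = either one-vs-rest AUC
  yb <- rep(1:2, each = 6)
  s <- withr::with_seed(13, runif(12))
  pb <- prediction_set(cbind(s, 1 - s, 0, 0, 0, 0), yb)
  roc <- suppressWarnings(per_class_roc(pb))
  agg <- suppressWarnings(aggregated_auc(pb))
  expect_equal(agg, roc$ACK$auc, tolerance = 1e-12)
  expect_equal(agg, roc$BCC$auc, tolerance = 1e-12)
})

test_that("one-vs-rest ROC AUC equals the Mann-Whitney statistic", {
  p <- random_prediction_set(30, seed = 21)
  roc <- suppressWarnings(per_class_roc(p))
  y <- as.integer(p$labels)
  for (c in which(!vapply(roc, is.null, logical(1)))) {
    pos <- p$probs[y == c, c]; neg <- p$probs[y != c, c]
    u <- sum(rank(c(pos, neg))[seq_along(pos)]) -
      length(pos) * (length(pos) + 1) / 2
    expect_equal(roc[[c]]$auc, u / (length(pos) * length(neg)),
                 tolerance = 1e-10)
    curve <- roc[[c]]$curve
    expect_equal(curve[1, ], data.frame(fpr = 0, tpr = 0), ignore_attr = TRUE)
    expect_equal(unlist(curve[nrow(curve), ]), c(fpr = 1, tpr = 1))
  }
})

test_that("confusion matrix conserves counts and links to accuracy", {
  p <- random_prediction_set(50, seed = 31)
  cm <- confusion(p)
  expect_equal(sum(cm), 50)
  expect_equal(unname(rowSums(cm)), unname(as.vector(table(p$labels))))
  expect_equal(sum(diag(cm)) / 50, accuracy(p), tolerance = 1e-12)
  cmn <- confusion(p, normalize = TRUE)
  present <- table(p$labels) > 0
  expect_true(all(abs(rowSums(cmn)[present] - 1) < 1e-12))
  # perfect predictions give a diagonal matrix of supports
  onehot <- function(i) { v <- rep(0.001, 6); v[i] <- 0.995; v / sum(v) }
  y <- rep(1:6, times = c(3, 1, 2, 2, 1, 3))
  perfect <- prediction_set(t(vapply(y, onehot, numeric(6))), y)
  expect_equal(unname(diag(confusion(perfect))), as.vector(table(y)))
  expect_equal(sum(confusion(perfect)) - sum(diag(confusion(perfect))), 0)
})

test_that("fold summaries report mean and sample SD", {
  mk <- function(acc, bacc, auc) {
    structure(list(acc = acc, bacc = bacc, auc = auc), class = "metrics_report")
  }
  s <- summarize_folds(list(mk(0.7, 0.6, 0.9), mk(0.8, 0.6, 0.9)))
  expect_equal(s$mean[s$metric == "acc"], 0.75)
  expect_equal(s$sd[s$metric == "acc"], sd(c(0.7, 0.8)))
  expect_equal(s$sd[s$metric == "bacc"], 0)
  expect_match(s$formatted[s$metric == "acc"], "^0\\.750 . 0\\.071$")
  expect_warning(s1 <- summarize_folds(list(mk(0.7, 0.6, 0.9))), "SD")
  expect_equal(s1$sd, rep(0, 3))
  # five-fold mean matches manual computation
  baccs <- c(0.71, 0.75, 0.69, 0.80, 0.77)
  s5 <- summarize_folds(lapply(baccs, function(b) mk(0.5, b, 0.9)))
  expect_equal(s5$mean[s5$metric == "bacc"], mean(baccs))
})

test_that("reports export to JSON and CSV", {
  p <- random_prediction_set(40, seed = 41)
  rep <- suppressWarnings(metrics_report(p))
  jf <- withr::local_tempfile(fileext = ".json")
  write_metrics_json(rep, jf)
  back <- jsonlite::read_json(jf)
  expect_equal(back$acc, rep$acc, tolerance = 1e-9)
  expect_equal(back$bacc, rep$bacc, tolerance = 1e-9)
  rf <- withr::local_tempfile(fileext = ".csv")
  cf <- withr::local_tempfile(fileext = ".csv")
  write_metrics_csv(rep, rf, cf)
  roc <- utils::read.csv(rf)
  expect_setequal(unique(roc$class),
                  names(rep$roc)[!vapply(rep$roc, is.null, logical(1))])
  cm <- utils::read.csv(cf, row.names = 1)
  expect_equal(sum(cm), 40)
})

test_that("prediction sets validate their invariants", {
  expect_error(prediction_set(matrix(1 / 6, 2, 5), c(1, 2)), "6 columns")
  bad <- matrix(1 / 6, 2, 6); bad[1, 1] <- 0.5
  expect_error(prediction_set(bad, c(1, 2)), "sum to 1")
  expect_error(prediction_set(matrix(1 / 6, 2, 6), c(1, 9)), "1\\.\\.6")
  expect_error(accuracy(structure(list(), class = "prediction_set")))
})
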