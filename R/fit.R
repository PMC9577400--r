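# Training: cross-entropy loss, SGD with momentum, reduce-on-plateau
# learning-rate schedule monitored on the training loss, and the mmf_net()
# fitting front end.

#' Training configuration
#'
#' Defaults follow the reference training procedure: SGD with initial
#' learning rate 0.001, learning rate multiplied by 0.1 when the best
#' training loss has not improved (by more than `plateau_tol`) for
#' `plateau_patience` consecutive epochs, and 100 epochs in total.
#' Momentum, weight decay and batch size are configurable (momentum 0.9,
#' no weight decay, batch 16 by default).
#'
#' @param epochs Number of training epochs (every epoch runs; there is no
#'   early stopping).
#' @param batch_size Minibatch size.
#' @param lr0 Initial learning rate.
#' @param momentum SGD momentum.
#' @param weight_decay L2 penalty coefficient.
#' @param plateau_factor Multiplicative learning-rate drop on plateau.
#' @param plateau_patience Consecutive non-improving epochs before a drop.
#' @param plateau_tol Minimum loss improvement that counts as progress.
#' @param lr_floor Lower bound on the learning rate.
#' @param grad_clip Global-norm gradient clipping threshold (`Inf`
#'   disables clipping).
#' @param augment Apply on-the-fly image augmentation during training
#'   (horizontal/vertical flips, color jitter, additive Gaussian noise,
#'   random contrast; pixel range preserved by clipping).
#' @param flip_p Probability of each flip.
#' @param jitter Brightness/saturation jitter amplitude (additive, in
#'   pixel-range units).
#' @param noise_sd Gaussian pixel noise SD (fraction of range).
#' @param contrast_range Range of the random contrast factor.
#' @param seed RNG seed for shuffling and augmentation.
#' @param verbose Print per-epoch loss.
#' @return An object of class `train_control`.
#' @export
train_control <- function(epochs = 100L, batch_size = 16L, lr0 = 0.001,
                          momentum = 0.9, weight_decay = 0,
                          plateau_factor = 0.1, plateau_patience = 10L,
                          plateau_tol = 1e-4, lr_floor = 1e-6,
                          grad_clip = 5,
                          augment = TRUE, flip_p = 0.5, jitter = 0.2,
                          noise_sd = 0.01, contrast_range = c(0.8, 1.25),
                          seed = 1L, verbose = FALSE) {
  stopifnot(lr0 > 0, plateau_factor > 0, plateau_factor < 1,
            plateau_patience >= 1, epochs >= 1, batch_size >= 1)
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr0 = lr0, momentum = momentum, weight_decay = weight_decay,
                 plateau_factor = plateau_factor,
                 plateau_patience = as.integer(plateau_patience),
                 plateau_tol = plateau_tol, lr_floor = lr_floor,
                 grad_clip = grad_clip,
                 augment = isTRUE(augment), flip_p = flip_p, jitter = jitter,
                 noise_sd = noise_sd, contrast_range = contrast_range,
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "train_control")
}

#' Reduce-on-plateau learning-rate scheduler
#'
#' Stateful scheduler: `step(loss)` registers one epoch's monitored loss
#' and returns the learning rate for the next epoch. When the best loss
#' seen so far has not improved by more than `tol` for `patience`
#' consecutive epochs, the rate is multiplied by `factor` (never below
#' `floor`) and the patience counter resets.
#'
#' @param lr0 Initial learning rate.
#' @param factor Multiplicative drop (0.1 reproduces the default schedule).
#' @param patience Non-improving epochs tolerated before a drop.
#' @param tol Minimum improvement of the best loss that resets patience.
#' @param floor Minimum learning rate.
#' @return List with functions `step(loss)` and `lr()`.
#' @export
plateau_scheduler <- function(lr0, factor = 0.1, patience = 10L, tol = 1e-4,
                              floor = 1e-6) {
  best <- Inf; wait <- 0L; lr <- lr0
  list(
    step = function(loss) {
      if (loss < best - tol) {
        best <<- loss; wait <<- 0L
      } else {
        wait <<- wait + 1L
        if (wait >= patience) {
          new_lr <- lr * factor
          # snap to the floor (tolerantly, so 1e-5 * 0.1 lands on 1e-6 exactly)
          lr <<- if (new_lr <= floor * (1 + 1e-9)) floor else new_lr
          wait <<- 0L
        }
      }
      lr
    },
    lr = function() lr
  )
}

#' Run an epoch loop under the plateau schedule
#'
#' Drives `epoch_fn(epoch, lr)` for exactly `control$epochs` epochs,
#' feeding each returned training loss to the plateau scheduler. This is
#' the schedule engine used by [mmf_net()]; exposing it separately lets a
#' scripted loss source verify the schedule contract.
#'
#' @param epoch_fn Function of `(epoch, lr)` returning that epoch's
#'   monitored (training) loss.
#' @param control A [train_control()].
#' @return List with per-epoch `loss` and `lr` traces, both of length
#'   `control$epochs`.
#' @export
run_schedule <- function(epoch_fn, control) {
  sch <- plateau_scheduler(control$lr0, control$plateau_factor,
                           control$plateau_patience, control$plateau_tol,
                           control$lr_floor)
  losses <- numeric(control$epochs)
  lrs <- numeric(control$epochs)
  lr <- control$lr0
  for (e in seq_len(control$epochs)) {
    lrs[e] <- lr
    losses[e] <- epoch_fn(e, lr)
    if (!is.finite(losses[e])) {
      stop("non-finite training loss at epoch ", e, "; aborting")
    }
    lr <- sch$step(losses[e])
  }
  list(loss = losses, lr = lrs)
}

# Inverse-frequency class weights normalized to mean 1.
inv_freq_weights <- function(y) {
  tab <- table(factor(y, levels = seq_len(6L)))
  w <- ifelse(tab > 0, 1 / as.numeric(tab), 0)
  w <- w / mean(w[tab > 0])
  as.numeric(w)
}

# One SGD step on a parameter tree; returns list(params, velocity).
sgd_step <- function(params, grads, velocity, lr, momentum, weight_decay) {
  if (weight_decay > 0) {
    grads <- tree_map2(grads, params, function(g, w) g + weight_decay * w)
  }
  velocity <- tree_map2(velocity, grads, function(v, g) momentum * v - lr * g)
  params <- tree_map2(params, velocity, function(w, v) w + v)
  list(params = params, velocity = velocity)
}

#' Fit the multimodal fusion network
#'
#' Trains the attention-guided fusion model on lesion images and encoded
#' clinical metadata with minibatch SGD, cross-entropy loss and the
#' reduce-on-plateau schedule. Metadata can be passed pre-encoded (a
#' numeric matrix) or as raw records together with a schema, in which case
#' encoding (and, if `config$normalize_meta`, standardization of numeric
#' attributes fitted on these training data) is handled internally and
#' frozen into the fitted object for prediction.
#'
#' @param images List of `image_size x image_size x 3` arrays in `[0, 1]`.
#' @param labels Class labels: factor/character over [lesion_classes()] or
#'   1-based integers.
#' @param meta Numeric matrix (one encoded row per image) or list of raw
#'   records (requires `schema`); `NULL` for image-only configurations.
#' @param config A [fusion_config()].
#' @param control A [train_control()].
#' @param schema A [meta_schema()] when `meta` is a list of raw records.
#' @return An object of class `mmf_net` (extending `mmf_model`) with the
#'   trained parameters, loss/learning-rate traces and featurization state.
#' @seealso [predict.mmf_net()], [run_cv()]
#' @export
mmf_net <- function(images, labels, meta = NULL, config = fusion_config(),
                    control = train_control(), schema = NULL) {
  y <- as.integer(as_lesion_factor(labels))
  n <- length(images)
  stopifnot(n >= 1L, length(y) == n)

  stats <- NULL
  if (config$use_meta) {
    if (is.null(meta)) stop("meta is required unless config$use_meta is FALSE")
    if (is.list(meta) && !is.data.frame(meta)) {
      if (is.null(schema)) stop("schema is required when meta is a record list")
      if (config$normalize_meta) stats <- fit_normalizer(schema, meta)
      meta <- encode_table(schema, meta, stats)
    }
    meta <- as.matrix(meta)
    if (nrow(meta) != n) stop("meta must have one row per image")
  }

  model <- mmf_model(config, meta_width = if (config$use_meta) ncol(meta))
  params <- model$params
  velocity <- tree_map(params, function(w) w * 0)
  w_cls <- if (config$class_weights) inv_freq_weights(y) else rep(1, 6L)

  # augmentation operates on raw [0, 1] images; channel normalization is
  # applied afterwards, so pre-normalize only when augmentation is off
  x_imgs <- if (!control$augment) lapply(images, image_to_vec, config = config)

  trace <- withr::with_seed(control$seed, {
    run_schedule(function(epoch, lr) {
      ord <- sample.int(n)
      total_loss <- 0
      for (start in seq(1L, n, by = control$batch_size)) {
        idx <- ord[start:min(start + control$batch_size - 1L, n)]
        grads <- NULL
        batch_loss <- 0
        for (i in idx) {
          x <- if (control$augment) {
            image_to_vec(augment_image(images[[i]], control), config)
          } else {
            x_imgs[[i]]
          }
          fw <- forward_sample(params, model$arch, config, x,
                               if (config$use_meta) as.numeric(meta[i, ]) else NULL)
          wi <- w_cls[y[i]]
          batch_loss <- batch_loss - wi * log(max(fw$probs[y[i]], 1e-12))
          dlogits <- wi * (fw$probs - as.numeric(seq_len(6L) == y[i]))
          g <- backward_sample(dlogits, fw, params, model$arch, config)
          grads <- if (is.null(grads)) g else tree_map2(grads, g, `+`)
        }
        grads <- tree_map(grads, function(g) g / length(idx))
        if (is.finite(control$grad_clip)) {
          gnorm <- sqrt(tree_sum(grads, function(g) g^2))
          if (gnorm > control$grad_clip) {
            grads <- tree_map(grads, function(g) g * control$grad_clip / gnorm)
          }
        }
        upd <- sgd_step(params, grads, velocity, lr, control$momentum,
                        control$weight_decay)
        params <<- upd$params # persists across epochs of the schedule
        velocity <<- upd$velocity
        total_loss <- total_loss + batch_loss
      }
      epoch_loss <- total_loss / n
      if (control$verbose) {
        message(sprintf("epoch %3d  lr %.2g  loss %.4f", epoch, lr, epoch_loss))
      }
      epoch_loss
    }, control)
  })

  model$params <- params
  out <- c(model, list(trace = trace, control = control, schema = schema,
                       normalizer = stats, n_train = n,
                       class_counts = table(factor(lesion_classes()[y],
                                                   levels = lesion_classes()))))
  class(out) <- c("mmf_net", "mmf_model")
  out
}

encode_meta_input <- function(object, meta) {
  if (is.list(meta) && !is.data.frame(meta)) {
    if (is.null(object$schema)) {
      stop("model was fitted on pre-encoded metadata; pass a numeric matrix")
    }
    meta <- encode_table(object$schema, meta, object$normalizer)
  }
  as.matrix(meta)
}

#' Predict lesion class probabilities or labels
#'
#' @param object A fitted [mmf_net()].
#' @param images List of image arrays (or a single array).
#' @param meta Encoded metadata matrix or list of raw records (featurized
#'   with the schema and normalization stats frozen at fit time).
#' @param type `"prob"` for the `n x 6` probability matrix, `"class"` for
#'   argmax labels (ties broken toward the lowest class index).
#' @param ... Unused.
#' @return Probability matrix or factor of predicted classes.
#' @export
predict.mmf_net <- function(object, images, meta = NULL,
                            type = c("prob", "class"), ...) {
  type <- match.arg(type)
  if (object$config$use_meta && !is.null(meta)) {
    meta <- encode_meta_input(object, meta)
  }
  probs <- mmf_forward(object, images, meta)
  if (type == "prob") return(probs)
  factor(lesion_classes()[apply(probs, 1, which.max)], levels = lesion_classes())
}

#' @export
print.mmf_net <- function(x, ...) {
  NextMethod()
  cat("  trained:", x$n_train, "samples,", length(x$trace$loss), "epochs;",
      "final loss", sprintf("%.4f", utils::tail(x$trace$loss, 1)), "\n")
  invisible(x)
}

#' @export
summary.mmf_net <- function(object, ...) {
  cat("Fitted multimodal fusion network\n\n")
  print(object)
  cat("\nTraining class counts:\n")
  print(object$class_counts)
  lr_drops <- which(diff(object$trace$lr) < 0)
  if (length(lr_drops)) {
    cat("\nLearning-rate drops after epochs:",
        paste(lr_drops, collapse = ", "), "\n")
  } else {
    cat("\nNo learning-rate drops occurred.\n")
  }
  invisible(object)
}

#' @export
coef.mmf_net <- function(object, ...) object$params

#' Plot the training loss and learning-rate trace
#'
#' @param x A fitted [mmf_net()].
#' @param ... Passed to [graphics::plot()].
#' @export
plot.mmf_net <- function(x, ...) {
  op <- graphics::par(mar = c(4, 4, 2, 4))
  on.exit(graphics::par(op))
  e <- seq_along(x$trace$loss)
  graphics::plot(e, x$trace$loss, type = "l", xlab = "epoch",
                 ylab = "training loss", main = "mmf_net training", ...)
  graphics::par(new = TRUE)
  graphics::plot(e, log10(x$trace$lr), type = "s", col = "grey50", lty = 2,
                 axes = FALSE, xlab = "", ylab = "")
  graphics::axis(4)
  graphics::mtext("log10 learning rate", side = 4, line = 2.5, col = "grey40")
  invisible(x)
}
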