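# Training: softmax cross-entropy loss, mini-batch SGD with momentum at a
# fixed learning rate, per-epoch curves, and stratified k-fold
# cross-validation. Everything is seeded (initialization, shuffling, fold
# assignment) so CPU runs are exactly reproducible.

#' Numerically stable softmax
#'
#' @param logits numeric vector, or matrix with one row per sample.
#' @return Probabilities of the same shape; each (row) sums to 1.
#' @export
softmax <- function(logits) {
  if (is.matrix(logits)) {
    z <- exp(logits - apply(logits, 1L, max))
    z / rowSums(z)
  } else {
    z <- exp(logits - max(logits))
    z / sum(z)
  }
}

#' Cross-entropy loss against a one-hot target
#'
#' `-sum_i y_i log P_i` with natural logarithm; probabilities are clamped
#' below at 1e-12 before the log, so the loss is finite and non-negative
#' and tends to 0 as the predicted distribution tends to the target.
#'
#' @param probs probability vector.
#' @param y one-hot vector of the same length.
#' @return Non-negative scalar.
#' @export
cross_entropy_loss <- function(probs, y) {
  if (length(probs) != length(y)) stop("probs and y differ in length")
  if (!all(y %in% c(0, 1)) || sum(y) != 1) {
    stop("validation error: y must be a one-hot vector")
  }
  -sum(y * log(pmax(probs, 1e-12)))
}

# Batched loss + gradient for training: logits (N x K), y integer labels.
softmax_ce_batch <- function(logits, y) {
  N <- nrow(logits); K <- ncol(logits)
  P <- softmax(logits)
  idx <- cbind(seq_len(N), y)
  loss <- -mean(log(pmax(P[idx], 1e-12)))
  dlogits <- P
  dlogits[idx] <- dlogits[idx] - 1
  list(loss = loss, dlogits = dlogits / N)
}

# ---- SGD ----------------------------------------------------------------

# Momentum buffers live on each module (m$opt_v, parallel to m$params).
sgd_step <- function(model, lr, momentum) {
  walk_modules(model, function(m) {
    if (!length(m$params)) return()
    if (is.null(m$opt_v)) {
      m$opt_v <- lapply(m$params, function(p) array(0, dim(as.array(p))))
    }
    for (nm in names(m$params)) {
      v <- momentum * m$opt_v[[nm]] + m$grads[[nm]]
      m$opt_v[[nm]] <- v
      m$params[[nm]] <- m$params[[nm]] - lr * v
    }
  })
}

# ---- precise batch-norm recalibration --------------------------------------

#' Re-estimate batch-norm statistics with the final weights
#'
#' During a short training run the exponential running statistics of batch
#' normalization lag the drifting activation distributions, which degrades
#' evaluation-mode forward passes. This computes exact population moments
#' of every normalization layer's input over the supplied data (forwarding
#' in batch-statistics mode, as in training) and writes them into the
#' running-statistics buffers ("precise BN").
#'
#' @param model a built network module (modified in place).
#' @param x rank-4 training images.
#' @param batch_size batch size for the statistics passes.
#' @return The model, invisibly.
#' @export
recalibrate_bn_stats <- function(model, x, batch_size = 32L) {
  walk_modules(model, function(m) {
    if (inherits(m, "batchnorm_layer") || inherits(m, "batchnorm1d_layer")) {
      m$stats_accum <- list(sum = numeric(m$C), sumsq = numeric(m$C), n = 0)
    }
  })
  N <- dim(x)[1]
  for (start in seq(1L, N, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, N)
    invisible(module_forward(model, x[idx, , , , drop = FALSE], training = TRUE))
  }
  walk_modules(model, function(m) {
    if (!is.null(m$stats_accum) && m$stats_accum$n > 1) {
      mu <- m$stats_accum$sum / m$stats_accum$n
      v <- m$stats_accum$sumsq / m$stats_accum$n - mu^2
      m$buffers$running_mean <- mu
      m$buffers$running_var <- pmax(v, 0) * m$stats_accum$n / (m$stats_accum$n - 1)
      m$stats_accum <- NULL
    }
  })
  invisible(model)
}

# ---- batched inference ----------------------------------------------------

#' Predict class labels for a batch of images
#'
#' @param model a built network module.
#' @param x rank-4 array `N x C x H x W`.
#' @param batch_size evaluation batch size.
#' @return Integer labels in `1:num_classes`.
#' @export
predict_labels <- function(model, x, batch_size = 64L) {
  N <- dim(x)[1]
  out <- integer(N)
  for (start in seq(1L, N, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, N)
    logits <- module_forward(model, x[idx, , , , drop = FALSE], training = FALSE)
    out[idx] <- max.col(logits, ties.method = "first")
  }
  out
}

#' Evaluate a model on labeled images
#'
#' @param model a built network module.
#' @param x rank-4 image array.
#' @param y integer labels in `1:K`.
#' @param K number of classes.
#' @param class_names optional class names.
#' @return An `eval_report` (see [per_class_metrics()]).
#' @export
evaluate_model <- function(model, x, y, K = max(y), class_names = NULL) {
  pred <- predict_labels(model, x)
  per_class_metrics(confusion_matrix(y, pred, K), class_names)
}

# ---- training loop --------------------------------------------------------

#' Train a model with mini-batch SGD at a fixed learning rate
#'
#' @param model a built network module (modified in place).
#' @param x,y training images (`N x C x H x W`) and integer labels.
#' @param cfg a [train_config()].
#' @param val_x,val_y optional validation set evaluated after every epoch.
#' @param verbose print one line per epoch.
#' @return List with the trained `model` and `history`, a data frame of
#'   per-epoch mean training loss, training accuracy and (when a
#'   validation set is given) validation accuracy.
#' @export
train <- function(model, x, y, cfg = train_config(), val_x = NULL,
                  val_y = NULL, verbose = FALSE) {
  N <- dim(x)[1]
  if (N < 1L) stop("empty training set")
  if (length(y) != N) stop("x and y disagree on the number of samples")
  K <- model$cfg$num_classes %||% max(y)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        train_acc = numeric(0), val_acc = numeric(0))
  for (epoch in seq_len(cfg$epochs)) {
    perm <- with_seed(cfg$seed * 1000L + epoch, function() sample(N))
    losses <- c()
    correct <- 0L
    for (start in seq(1L, N, by = cfg$batch_size)) {
      idx <- perm[start:min(start + cfg$batch_size - 1L, N)]
      xb <- x[idx, , , , drop = FALSE]
      yb <- y[idx]
      zero_grads(model)
      logits <- module_forward(model, xb, training = TRUE)
      lb <- softmax_ce_batch(logits, yb)
      if (!is.finite(lb$loss)) {
        stop(sprintf("NaN/Inf loss at epoch %d (lr = %g); reduce the learning rate",
                     epoch, cfg$lr))
      }
      losses <- c(losses, lb$loss)
      correct <- correct + sum(max.col(logits, ties.method = "first") == yb)
      module_backward(model, lb$dlogits)
      sgd_step(model, cfg$lr, cfg$momentum)
    }
    val_acc <- NA_real_
    if (!is.null(val_x)) {
      val_acc <- mean(predict_labels(model, val_x) == val_y)
    }
    history <- rbind(history, data.frame(
      epoch = epoch, train_loss = mean(losses), train_acc = correct / N,
      val_acc = val_acc))
    if (verbose) {
      message(sprintf("epoch %2d  loss %.4f  train acc %.3f  val acc %s",
                      epoch, mean(losses), correct / N,
                      ifelse(is.na(val_acc), "-", sprintf("%.3f", val_acc))))
    }
  }
  if (isTRUE(cfg$bn_recalibrate)) {
    recalibrate_bn_stats(model, x, cfg$batch_size)
    if (!is.null(val_x)) {
      history$val_acc[cfg$epochs] <- mean(predict_labels(model, val_x) == val_y)
    }
  }
  list(model = model, history = history)
}

# ---- k-fold cross-validation ----------------------------------------------

#' Stratified k-fold assignment
#'
#' @param labels per-item class labels.
#' @param k number of folds (>= 2).
#' @param seed shuffle seed.
#' @return Integer vector of fold ids in `1:k`, one per item; within every
#'   class the fold sizes differ by at most one.
#' @export
make_stratified_folds <- function(labels, k, seed = 1L) {
  if (k < 2L) stop("k must be >= 2")
  folds <- integer(length(labels))
  ulab <- unique(labels)
  for (ci in seq_along(ulab)) {
    idx <- which(labels == ulab[ci])
    if (length(idx) < k) stop("k exceeds the number of items in class ", ulab[ci])
    perm <- with_seed(seed + ci, function() sample(idx))
    folds[perm] <- rep_len(seq_len(k), length(perm))
  }
  folds
}

#' k-fold cross-validation of a network configuration
#'
#' Stratified k-fold partition; one model per fold, trained from a fresh
#' seeded initialization on the other folds and evaluated on the held-out
#' fold; metrics are averaged across folds (models are never averaged).
#'
#' @param x,y dataset images and integer labels.
#' @param net_cfg a [net_config()] used to build each fold's model.
#' @param cfg a [train_config()]; `cfg$k` folds.
#' @param class_names optional class names for the reports.
#' @param verbose print per-epoch progress.
#' @return List with `fold_reports` (one `eval_report` per fold),
#'   `mean_accuracy`, `fold_ids` and per-fold training `histories`.
#' @export
run_kfold_cv <- function(x, y, net_cfg, cfg = train_config(),
                         class_names = NULL, verbose = FALSE) {
  folds <- make_stratified_folds(y, cfg$k, cfg$seed)
  reports <- vector("list", cfg$k)
  histories <- vector("list", cfg$k)
  for (f in seq_len(cfg$k)) {
    tr <- which(folds != f)
    va <- which(folds == f)
    model <- build_xodfcanet(net_cfg, seed = cfg$seed + f)
    fold_cfg <- cfg
    fold_cfg$seed <- cfg$seed + 100L * f
    fit <- train(model, x[tr, , , , drop = FALSE], y[tr], fold_cfg,
                 val_x = x[va, , , , drop = FALSE], val_y = y[va],
                 verbose = verbose)
    reports[[f]] <- evaluate_model(fit$model, x[va, , , , drop = FALSE],
                                   y[va], K = net_cfg$num_classes,
                                   class_names = class_names)
    histories[[f]] <- fit$history
  }
  list(fold_reports = reports,
       mean_accuracy = mean(vapply(reports, function(r) r$accuracy, numeric(1))),
       fold_ids = folds,
       histories = histories)
}
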