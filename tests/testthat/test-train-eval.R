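# Loss functions, metrics, k-fold machinery and the training loop.

test_that("softmax: symmetry, shift invariance, closed form", {
  expect_equal(softmax(c(0, 0, 0)), rep(1 / 3, 3))
  set.seed(51)
  z <- rnorm(5)
  expect_equal(softmax(z + 13.7), softmax(z), tolerance = 1e-9)
  expect_equal(softmax(log(1:3)), c(1, 2, 3) / 6, tolerance = 1e-12)
  m <- softmax(matrix(rnorm(12), 4, 3))
  expect_equal(rowSums(m), rep(1, 4), tolerance = 1e-9)
  expect_true(all(m > 0))
})

test_that("cross-entropy: exact values and one-hot validation", {
  expect_equal(cross_entropy_loss(c(0, 1, 0), c(0, 1, 0)), 0, tolerance = 1e-9)
  expect_equal(cross_entropy_loss(rep(1 / 3, 3), c(1, 0, 0)), log(3), tolerance = 1e-9)
  expect_equal(cross_entropy_loss(rep(1 / 3, 3), c(0, 0, 1)), log(3), tolerance = 1e-9)
  expect_equal(cross_entropy_loss(c(0.2, 0.3, 0.5), c(0, 0, 1)), -log(0.5),
               tolerance = 1e-9)
  expect_error(cross_entropy_loss(c(0.5, 0.5), c(1, 1)), "one-hot")
  expect_error(cross_entropy_loss(c(0.5, 0.5), c(0.5, 0.5)), "one-hot")
  # clamping keeps the loss finite on a degenerate prediction
  expect_true(is.finite(cross_entropy_loss(c(1, 0, 0), c(0, 1, 0))))
})

test_that("confusion matrix and per-class metrics reproduce hand counts", {
  cm <- matrix(c(9, 1, 0,
                 0, 8, 2,
                 1, 0, 9), 3, 3, byrow = TRUE)
  rep_ <- per_class_metrics(cm)
  expect_equal(rep_$metrics$precision[1], 0.9)   # TP 9, FP 1
  expect_equal(rep_$metrics$recall[1], 0.9)      # TP 9, FN 1
  expect_equal(rep_$metrics$specificity[1], 0.95) # TN 19, FP 1
  expect_equal(rep_$accuracy, 26 / 30)

  cm2 <- confusion_matrix(c(1, 1, 2, 2), c(1, 2, 2, 2), K = 2)
  expect_equal(cm2, matrix(c(1L, 0L, 1L, 2L), 2, 2))
  expect_equal(per_class_metrics(cm2)$accuracy, 0.75)

  perfect <- confusion_matrix(c(1, 2, 3), c(1, 2, 3), K = 3)
  repp <- per_class_metrics(perfect)
  expect_equal(repp$metrics$precision, rep(1, 3))
  expect_equal(repp$metrics$recall, rep(1, 3))
  expect_equal(repp$metrics$specificity, rep(1, 3))
})

test_that("metrics: conservation, relabeling invariance, NA on empty cells", {
  set.seed(52)
  y <- sample(1:3, 60, replace = TRUE)
  p <- sample(1:3, 60, replace = TRUE)
  cm <- confusion_matrix(y, p, 3)
  expect_equal(sum(cm), 60)
  expect_equal(rowSums(cm), as.numeric(table(factor(y, 1:3))), ignore_attr = TRUE)
  # simultaneous relabeling permutes the per-class rows but keeps accuracy
  perm <- c(3, 1, 2)
  cm_perm <- confusion_matrix(perm[y], perm[p], 3)
  r1 <- per_class_metrics(cm); r2 <- per_class_metrics(cm_perm)
  expect_equal(r1$accuracy, r2$accuracy)
  # old class c becomes new class perm[c]
  expect_equal(r2$metrics$precision[perm], r1$metrics$precision)
  expect_equal(r2$metrics$recall[perm], r1$metrics$recall)
  expect_equal(r2$metrics$specificity[perm], r1$metrics$specificity)
  # never-predicted class: precision undefined, not zero
  cm3 <- confusion_matrix(c(1, 2, 2), c(1, 1, 1), K = 2)
  expect_true(is.na(per_class_metrics(cm3)$metrics$precision[2]))
  expect_error(confusion_matrix(1:3, 1:2), "length")
})

test_that("stratified k-fold partitions are exact and deterministic", {
  y <- rep(1:2, each = 4)
  f <- make_stratified_folds(y, 4, seed = 9)
  expect_equal(sort(unique(f)), 1:4)
  for (k in 1:4) expect_equal(sum(f == k), 2)           # folds of 2
  for (cls in 1:2) expect_equal(as.numeric(table(f[y == cls])), rep(1, 4))
  expect_identical(f, make_stratified_folds(y, 4, seed = 9))
  expect_false(identical(f, make_stratified_folds(y, 4, seed = 10)))
  expect_error(make_stratified_folds(rep(1, 3), 4), "exceeds")
})

tiny_train_cfg <- function() {
  net_config(num_classes = 3, input_size = c(3, 32, 32),
             widths = c(8, 16, 32, 64), blocks = c(1, 1, 1, 1),
             odconv = list(n = 2, gamma = 0.25), ca = list(r = 4))
}

test_that("one small gradient step reduces the loss on a single sample", {
  set.seed(53)
  net <- build_xodfcanet(tiny_train_cfg(), seed = 21)
  x <- array(rnorm(1 * 3 * 32 * 32), c(1, 3, 32, 32))
  y <- 2L
  loss_of <- function(model, training) {
    logits <- module_forward(model, x, training = training)
    -log(softmax(as.numeric(logits))[y])
  }
  zero_grads(net)
  logits <- module_forward(net, x, training = TRUE)
  l0 <- -log(softmax(as.numeric(logits))[y])
  p <- softmax(as.numeric(logits))
  d <- matrix(p, 1); d[1, y] <- d[1, y] - 1
  module_backward(net, d)
  odfcanet:::sgd_step(net, lr = 1e-3, momentum = 0)
  l1 <- loss_of(net, TRUE)
  expect_lt(l1, l0)
})

test_that("identical seeds give identical training curves", {
  ds <- tiny_cxr_dataset(per_class = 4, size = 32, seed = 5, img_size = 64)
  cfg <- tiny_train_cfg()
  tc <- train_config(epochs = 2, lr = 0.01, batch_size = 4, seed = 77)
  run <- function() {
    model <- build_xodfcanet(cfg, seed = 42)
    train(model, ds$x, ds$y, tc)$history
  }
  h1 <- run(); h2 <- run()
  expect_identical(h1$train_loss, h2$train_loss)
  expect_identical(h1$train_acc, h2$train_acc)
})

test_that("a width-reduced model fits 30 separable images in a few epochs", {
  ds <- tiny_cxr_dataset(per_class = 10, size = 48, seed = 6, img_size = 96)
  cfg <- net_config(num_classes = 3, input_size = c(3, 48, 48),
                    widths = c(16, 32, 64, 128), blocks = c(1, 1, 1, 1),
                    odconv = list(n = 2, gamma = 0.25), ca = list(r = 8))
  model <- build_xodfcanet(cfg, seed = 38)
  tc <- train_config(epochs = 5, lr = 0.02, batch_size = 10, seed = 8)
  fit <- train(model, ds$x, ds$y, tc)
  # the fitted model classifies its whole training set correctly
  expect_equal(mean(predict_labels(fit$model, ds$x) == ds$y), 1.0)
  expect_equal(nrow(fit$history), 5)
  expect_true(all(diff(fit$history$epoch) == 1))
  expect_gt(fit$history$train_acc[5], 0.85)
})

test_that("training aborts with a diagnostic on a non-finite loss", {
  ds <- tiny_cxr_dataset(per_class = 2, size = 32, seed = 5, img_size = 64)
  model <- build_xodfcanet(tiny_train_cfg(), seed = 1)
  model$children$fc$params$weight[] <- NaN  # forces a NaN loss
  tc <- train_config(epochs = 1, lr = 0.01, batch_size = 6, seed = 1)
  expect_error(train(model, ds$x, ds$y, tc), "loss")
})

test_that("empty training sets are rejected", {
  model <- build_xodfcanet(tiny_train_cfg(), seed = 1)
  expect_error(train(model, array(0, c(0, 3, 32, 32)), integer(0)), "empty")
})
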