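# Network assembly and cost accounting.

tiny_cfg <- function(...) {
  net_config(num_classes = 3, input_size = c(3, 32, 32),
             widths = c(4, 8, 16, 32), blocks = c(1, 1, 1, 1),
             odconv = list(n = 2, gamma = 0.5), ca = list(r = 2), ...)
}

test_that("residual block obeys the shape contract", {
  set.seed(31)
  cfg <- net_config(odconv = list(n = 2, gamma = 0.5))
  b1 <- build_odconv_resblock(8, 8, 1, cfg)
  x <- array(rnorm(1 * 8 * 14 * 14), c(1, 8, 14, 14))
  expect_equal(dim(module_forward(b1, x)), c(1, 8, 14, 14))

  b2 <- build_odconv_resblock(8, 16, 2, cfg)
  expect_equal(dim(module_forward(b2, x)), c(1, 16, 7, 7))

  expect_error(build_odconv_resblock(8, 8, 3, cfg), "invalid stride")
})

test_that("residual block maps zero input to zero output", {
  set.seed(32)
  b <- build_odconv_resblock(4, 8, 2, net_config(odconv = list(n = 2, gamma = 0.5)))
  x <- array(0, c(2, 4, 8, 8))
  # evaluation mode: fresh batch-norm buffers are the identity transform,
  # biases are zero, attention gates scale zeros by constants
  expect_true(all(module_forward(b, x, training = FALSE) == 0))
})

test_that("assembled network emits one logit row per sample", {
  set.seed(33)
  net <- build_xodfcanet(tiny_cfg(), seed = 5)
  x <- array(rnorm(2 * 3 * 32 * 32), c(2, 3, 32, 32))
  logits <- forward_logits(net, x)
  expect_equal(dim(logits), c(2, 3))
  expect_true(all(is.finite(logits)))
})

test_that("stage output spatial sizes at 224x224 are 56, 28, 14, 7", {
  cfg <- net_config(widths = c(8, 16, 32, 64), blocks = c(1, 1, 1, 1),
                    odconv = list(n = 1, gamma = 0.5))
  net <- build_xodfcanet(cfg, seed = 1)
  s <- model_summary(net)
  rows <- s$layers
  get_hw <- function(layer) {
    out <- rows$output[rows$layer == layer]
    as.integer(strsplit(out, "x")[[1]][2])
  }
  expect_equal(get_hw("stage1.block1.relu_out"), 56)
  expect_equal(get_hw("stage2.block1.relu_out"), 28)
  expect_equal(get_hw("stage3.block1.relu_out"), 14)
  expect_equal(get_hw("stage4.block1.relu_out"), 7)
  expect_equal(get_hw("stem_conv"), 112)
})

test_that("summary breakdown accounts for every trainable scalar exactly once", {
  net <- build_xodfcanet(tiny_cfg(), seed = 2)
  s <- model_summary(net)
  expect_equal(sum(s$layers$params), count_parameters(net))
  expect_equal(s$total_params, count_parameters(net))
  # independent recount from the flat parameter list
  expect_equal(count_parameters(net),
               sum(vapply(module_param_list(net), length, numeric(1))))
  for (b in c("build_resnet18_baseline", "build_resnet50_baseline")) {
    mdl <- get(b)(3, seed = 1)
    sm <- model_summary(mdl, c(3, 224, 224))
    expect_equal(sum(sm$layers$params), count_parameters(mdl))
  }
})

test_that("accountant agrees with an independent closed-form recomputation", {
  set.seed(34)
  grid <- expand.grid(w0 = c(8, 16), n = c(1, 2), gamma = c(0.25, 0.5),
                      b4 = c(1, 2), r = c(2, 4))
  picks <- grid[sample(nrow(grid), 10), ]
  for (i in seq_len(nrow(picks))) {
    g <- picks[i, ]
    cfg <- net_config(input_size = c(3, 64, 64),
                      widths = g$w0 * c(1, 2, 4, 8),
                      blocks = c(1, 1, 1, g$b4),
                      odconv = list(n = g$n, gamma = g$gamma),
                      ca = list(r = g$r))
    net <- build_xodfcanet(cfg, seed = i)
    s <- model_summary(net)
    ref <- closed_form_cost(cfg)
    expect_equal(s$total_params, ref$params)
    expect_equal(s$total_macs, ref$macs)
  }
})

test_that("single-layer MAC formulas match closed form", {
  m <- conv_layer(1, 2, 3, stride = 1, pad = 1)
  expect_equal(count_macs(m, c(1, 8, 8)), 8 * 8 * 2 * 1 * 9)
  fc <- linear_layer(512, 3)
  expect_equal(count_parameters(fc), 512 * 3 + 3)
  expect_equal(count_macs(fc, 512), 512 * 3)
})

test_that("building twice with one seed is bitwise identical", {
  cfg <- tiny_cfg()
  p1 <- module_param_list(build_xodfcanet(cfg, seed = 99))
  p2 <- module_param_list(build_xodfcanet(cfg, seed = 99))
  expect_identical(p1, p2)
  p3 <- module_param_list(build_xodfcanet(cfg, seed = 100))
  expect_false(identical(p1, p3))
})

test_that("classifier-head scaling changes exactly the head parameters", {
  cfg3 <- tiny_cfg()
  cfg1000 <- net_config(num_classes = 1000, input_size = c(3, 32, 32),
                        widths = c(4, 8, 16, 32), blocks = c(1, 1, 1, 1),
                        odconv = list(n = 2, gamma = 0.5), ca = list(r = 2))
  D <- cfg3$widths[4]
  n3 <- count_parameters(build_xodfcanet(cfg3, seed = 1))
  n1000 <- count_parameters(build_xodfcanet(cfg1000, seed = 1))
  expect_equal(n1000 - n3, D * 997 + 997)
})

test_that("configuration invariants are enforced with the offending field named", {
  expect_error(net_config(widths = c(64, 128, 256, 511)), "widths")
  expect_error(net_config(widths = c(64, 128, 256)), "widths")
  expect_error(net_config(blocks = c(2, 2, 2)), "blocks")
  expect_error(net_config(num_classes = 1), "num_classes")
  expect_error(net_config(odconv = list(gamma = 2)), "gamma")
  expect_error(net_config(widths = c(4, 8, 16, 32), ca = list(r = 8)), "ca.r")
})

test_that("network configurations round-trip through YAML", {
  cfg <- xodfcanet_reference_config()
  path <- tempfile(fileext = ".yaml")
  write_net_config(cfg, path)
  cfg2 <- read_net_config(path)
  expect_equal(unclass(cfg)[order(names(cfg))], unclass(cfg2)[order(names(cfg2))])
})

test_that("full network gradients agree with numerical differentiation", {
  set.seed(35)
  net <- build_xodfcanet(tiny_cfg(), seed = 3)
  x <- array(rnorm(2 * 3 * 32 * 32), c(2, 3, 32, 32))
  expect_lt(grad_check_worst(net, x, npick = 2), 1e-4)
})
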