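# Omni-dimensional dynamic convolution: attention pipeline, effective
# kernel aggregation, forward pass, and parameter accounting.

test_that("attention head output sizes match the four kernel dimensions", {
  head <- omni_attention_head(c_in = 64, c_out = 64, k = 3, n = 4, init = "zero")
  expect_equal(nrow(head$w_s), 9)    # spatial head: k*k
  expect_equal(nrow(head$w_c), 64)   # input-channel head
  expect_equal(nrow(head$w_f), 64)   # output-channel head
  expect_equal(nrow(head$w_w), 4)    # kernel head
  expect_equal(nrow(head$w_sq), max(1, floor(64 / 16)))
})

test_that("zero input through a zero head gives attention 0.5 everywhere", {
  head <- omni_attention_head(2, 3, 3, 2, gamma = 0.5, init = "zero")
  x <- array(0, c(2, 2, 4, 4))
  a <- compute_attention(x, head)
  expect_true(all(a$alpha_s == 0.5))
  expect_true(all(a$alpha_c == 0.5))
  expect_true(all(a$alpha_f == 0.5))
  expect_true(all(a$alpha_w == 0.5))
})

test_that("attention values lie strictly in (0,1) for random finite inputs", {
  set.seed(101)
  for (rep in 1:20) {
    c_in <- sample(1:5, 1); c_out <- sample(1:5, 1)
    n <- sample(1:3, 1)
    head <- omni_attention_head(c_in, c_out, 3, n, gamma = 0.5)
    x <- array(rnorm(2 * c_in * 4 * 4, sd = 5), c(2, c_in, 4, 4))
    a <- compute_attention(x, head)
    vals <- c(a$alpha_s, a$alpha_c, a$alpha_f, a$alpha_w)
    expect_true(all(vals > 0 & vals < 1))
  }
})

test_that("compute_attention matches a straight-line oracle", {
  set.seed(7)
  head <- omni_attention_head(4, 3, 3, 2, gamma = 0.5)
  x <- array(rnorm(1 * 4 * 5 * 5), c(1, 4, 5, 5))
  a <- compute_attention(x, head)
  o <- naive_attention(array(x[1, , , ], c(4, 5, 5)), head)
  expect_equal(as.numeric(a$alpha_s[1, , ]), o$alpha_s, tolerance = 1e-6)
  expect_equal(as.numeric(a$alpha_c[1, ]), o$alpha_c, tolerance = 1e-6)
  expect_equal(as.numeric(a$alpha_f[1, ]), o$alpha_f, tolerance = 1e-6)
  expect_equal(as.numeric(a$alpha_w[1, ]), o$alpha_w, tolerance = 1e-6)
})

test_that("compute_attention rejects channel mismatches, naming both counts", {
  head <- omni_attention_head(4, 4, 3, 2)
  x <- array(0, c(1, 3, 4, 4))
  expect_error(compute_attention(x, head), "3.*4|4.*3")
})

test_that("effective kernel: kernel-index attention acts as a selector", {
  set.seed(11)
  kb <- kernel_bank(array(rnorm(2 * 3 * 2 * 3 * 3), c(2, 3, 2, 3, 3)))
  attn <- attention_quadruple(alpha_s = matrix(1, 3, 3), alpha_c = rep(1, 2),
                              alpha_f = rep(1, 3), alpha_w = c(1, 0))
  expect_equal(effective_kernel(attn, kb),
               array(kb$kernels[1, , , , ], c(3, 2, 3, 3)))
})

test_that("effective kernel: equal kernels are preserved by a convex mix", {
  set.seed(12)
  w1 <- array(rnorm(3 * 2 * 3 * 3), c(3, 2, 3, 3))
  kernels <- array(0, c(2, 3, 2, 3, 3))
  kernels[1, , , , ] <- w1; kernels[2, , , , ] <- w1
  kb <- kernel_bank(kernels)
  attn <- attention_quadruple(matrix(1, 3, 3), rep(1, 2), rep(1, 3), c(0.5, 0.5))
  expect_equal(effective_kernel(attn, kb), w1, tolerance = 1e-12)
})

test_that("effective kernel matches the nested-loop oracle", {
  set.seed(13)
  kernels <- array(rnorm(3 * 2 * 2 * 1 * 1), c(3, 2, 2, 1, 1))
  kb <- kernel_bank(kernels)
  a_s <- matrix(runif(1), 1, 1); a_c <- runif(2); a_f <- runif(2); a_w <- runif(3)
  attn <- attention_quadruple(a_s, a_c, a_f, a_w)
  expect_equal(effective_kernel(attn, kb),
               naive_effective_kernel(a_s, a_c, a_f, a_w, kernels),
               tolerance = 1e-12)
})

test_that("odconv forward: zero input yields zero output", {
  set.seed(14)
  head <- omni_attention_head(2, 3, 3, 2, gamma = 0.5)
  kb <- kernel_bank(array(rnorm(2 * 3 * 2 * 3 * 3), c(2, 3, 2, 3, 3)),
                    stride = 1, padding = 1)
  out <- odconv_forward(array(0, c(2, 2, 5, 5)), kb, head)
  expect_true(all(out == 0))
  expect_equal(dim(out), c(2, 3, 5, 5))
})

test_that("odconv forward degenerates to static convolution at n=1, unit attention", {
  set.seed(15)
  for (rep in 1:5) {
    c_in <- sample(1:3, 1); c_out <- sample(1:3, 1)
    w <- array(rnorm(c_out * c_in * 9), c(1, c_out, c_in, 3, 3))
    kb <- kernel_bank(w, stride = 1, padding = 1)
    # saturate every sigmoid head far into its upper tail via huge biases
    head <- omni_attention_head(c_in, c_out, 3, 1, gamma = 1, init = "zero")
    for (nm in c("b_s", "b_c", "b_f", "b_w")) head[[nm]][] <- 1e4
    x <- array(rnorm(2 * c_in * 6 * 6), c(2, c_in, 6, 6))
    expect_equal(odconv_forward(x, kb, head),
                 naive_conv(x, array(w[1, , , , ], dim(w)[2:5]), 1, 1),
                 tolerance = 1e-6)
  }
})

test_that("odconv forward matches the materialize-then-slide oracle", {
  set.seed(16)
  kernels <- array(rnorm(2 * 3 * 2 * 3 * 3), c(2, 3, 2, 3, 3))
  kb <- kernel_bank(kernels, stride = 1, padding = 1)
  head <- omni_attention_head(2, 3, 3, 2, gamma = 0.5)
  x <- array(rnorm(1 * 2 * 6 * 6), c(1, 2, 6, 6))
  out <- odconv_forward(x, kb, head)
  a <- compute_attention(x, head)
  keff <- effective_kernel(attn_sample(a, 1), kb)
  expect_equal(out, naive_conv(x, keff, 1, 1), tolerance = 1e-6)
})

test_that("odconv with input-independent attention is linear in the input", {
  # a zero-initialized head gives the same (constant) attention for any
  # input, freezing the quadruple; superposition must then hold
  set.seed(17)
  kb <- kernel_bank(array(rnorm(2 * 3 * 2 * 3 * 3), c(2, 3, 2, 3, 3)),
                    stride = 1, padding = 1)
  head <- omni_attention_head(2, 3, 3, 2, gamma = 0.5, init = "zero")
  x1 <- array(rnorm(2 * 2 * 5 * 5), c(2, 2, 5, 5))
  x2 <- array(rnorm(2 * 2 * 5 * 5), c(2, 2, 5, 5))
  lhs <- odconv_forward(2.5 * x1 - 0.7 * x2, kb, head)
  rhs <- 2.5 * odconv_forward(x1, kb, head) - 0.7 * odconv_forward(x2, kb, head)
  expect_equal(lhs, rhs, tolerance = 1e-5)
})

test_that("odconv parameter count: closed-form examples", {
  kb <- kernel_bank(array(0, c(2, 4, 4, 3, 3)))
  head <- omni_attention_head(4, 4, 3, 2, gamma = 1 / 4, init = "zero")
  expect_equal(odconv_param_count(kb, head), 331)

  kb1 <- kernel_bank(array(0, c(1, 1, 1, 1, 1)))
  head1 <- omni_attention_head(1, 1, 1, 1, gamma = 1, init = "zero")
  expect_equal(odconv_param_count(kb1, head1), 11)
})

test_that("doubling n adds exactly the predicted kernel and head parameters", {
  for (cfg in list(c(c_in = 3, c_out = 5, k = 3), c(c_in = 4, c_out = 2, k = 1))) {
    for (n in c(1L, 3L)) {
      gamma <- 1 / 2
      s <- max(1, floor(cfg[["c_in"]] * gamma))
      mk <- function(nn) {
        odconv_param_count(
          kernel_bank(array(0, c(nn, cfg[["c_out"]], cfg[["c_in"]], cfg[["k"]], cfg[["k"]]))),
          omni_attention_head(cfg[["c_in"]], cfg[["c_out"]], cfg[["k"]], nn,
                              gamma = gamma, init = "zero"))
      }
      delta <- mk(2L * n) - mk(n)
      expect_equal(delta,
                   n * cfg[["c_out"]] * cfg[["c_in"]] * cfg[["k"]]^2 + (s + 1) * n)
    }
  }
})

test_that("closed-form count equals the scalars registered by the layer", {
  m <- odconv_layer(5, 7, k = 3, n = 3, gamma = 1 / 4)
  expect_equal(odconv_param_count(odconv_layer_bank(m), odconv_layer_head(m)),
               count_parameters(m))
})

test_that("odconv layer gradients agree with numerical differentiation", {
  set.seed(18)
  m <- odconv_layer(3, 4, k = 3, stride = 2, pad = 1, n = 2, gamma = 0.5)
  x <- array(rnorm(2 * 3 * 6 * 6), c(2, 3, 6, 6))
  expect_lt(grad_check_worst(m, x), 1e-5)
  m2 <- odconv_layer(3, 4, k = 3, n = 3, gamma = 0.5, kernel_attention = "softmax")
  expect_lt(grad_check_worst(m2, x), 1e-5)
})
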