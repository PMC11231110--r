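# Coordinate attention and the FCA fusion head.

test_that("channel global pooling is the spatial arithmetic mean", {
  x <- array(0, c(1, 1, 2, 2))
  x[1, 1, , ] <- matrix(c(1, 3, 2, 4), 2, 2)  # [[1,2],[3,4]] by row
  expect_equal(channel_global_pool(x)[1, 1], 2.5)

  xc <- array(7.25, c(2, 3, 4, 5))
  expect_true(all(channel_global_pool(xc) == 7.25))

  set.seed(21)
  xr <- array(rnorm(2 * 3 * 4 * 5), c(2, 3, 4, 5))
  loop <- matrix(0, 2, 3)
  for (n in 1:2) for (c in 1:3) {
    s <- 0
    for (i in 1:4) for (j in 1:5) s <- s + xr[n, c, i, j]
    loop[n, c] <- s / 20
  }
  expect_equal(channel_global_pool(xr), loop, tolerance = 1e-7)
})

test_that("directional pools average the correct axes", {
  x <- array(0, c(1, 1, 2, 3))
  x[1, 1, 1, ] <- c(1, 2, 3)
  x[1, 1, 2, ] <- c(4, 5, 6)
  p <- directional_pools(x)
  expect_equal(dim(p$h), c(1, 1, 2, 1))
  expect_equal(dim(p$w), c(1, 1, 1, 3))
  expect_equal(as.numeric(p$h), c(2, 5))
  expect_equal(as.numeric(p$w), c(2.5, 3.5, 4.5))

  xc <- array(3.5, c(2, 2, 3, 4))
  pc <- directional_pools(xc)
  expect_true(all(pc$h == 3.5) && all(pc$w == 3.5))
})

test_that("directional pools and global pooling satisfy the mean identity", {
  set.seed(22)
  x <- array(rnorm(3 * 4 * 5 * 6), c(3, 4, 5, 6))
  p <- directional_pools(x)
  g <- channel_global_pool(x)
  expect_equal(apply(p$h, c(1, 2), mean), g, tolerance = 1e-12)
  expect_equal(apply(p$w, c(1, 2), mean), g, tolerance = 1e-12)
})

test_that("coordinate attention preserves shape across a grid of sizes", {
  set.seed(23)
  for (C in c(4, 8, 16)) {
    for (hw in list(c(7, 7), c(14, 7), c(7, 56))) {
      m <- coordatt_layer(C, r = 4)
      x <- array(rnorm(2 * C * hw[1] * hw[2]), c(2, C, hw[1], hw[2]))
      expect_equal(dim(module_forward(m, x)), dim(x))
    }
  }
})

test_that("gates attenuate: output keeps the sign and shrinks the magnitude", {
  set.seed(24)
  m <- coordatt_layer(4, r = 2)
  x <- array(rnorm(2 * 4 * 6 * 6), c(2, 4, 6, 6))
  out <- module_forward(m, x)
  nz <- x != 0
  expect_true(all(sign(out[nz]) == sign(x[nz])))
  expect_true(all(abs(out[nz]) < abs(x[nz])))
})

test_that("functional coordinate attention matches a straight-line oracle", {
  set.seed(25)
  C <- 4; H <- 4; W <- 4; r <- 2; cr <- C %/% r
  p <- coord_att_params(C, r,
                        w_reduce = matrix(rnorm(cr * C), cr, C),
                        b_reduce = rnorm(cr),
                        w_h = matrix(rnorm(C * cr), C, cr), b_h = rnorm(C),
                        w_w = matrix(rnorm(C * cr), C, cr), b_w = rnorm(C))
  x <- array(rnorm(1 * C * H * W), c(1, C, H, W))
  out <- coordatt_forward(x, p)
  expect_equal(dim(out), dim(x))

  # oracle: explicit per-position recomputation for the single sample
  sig <- function(t) 1 / (1 + exp(-t))
  hprof <- matrix(0, C, H); wprof <- matrix(0, C, W)
  for (c in seq_len(C)) {
    for (i in seq_len(H)) hprof[c, i] <- mean(x[1, c, i, ])
    for (j in seq_len(W)) wprof[c, j] <- mean(x[1, c, , j])
  }
  u <- cbind(hprof, wprof)                       # C x (H+W)
  v <- pmax(p$w_reduce %*% u + p$b_reduce, 0)    # cr x (H+W)
  s_h <- sig(p$w_h %*% v[, seq_len(H), drop = FALSE] + p$b_h)
  s_w <- sig(p$w_w %*% v[, H + seq_len(W), drop = FALSE] + p$b_w)
  expected <- x
  for (c in seq_len(C)) for (i in seq_len(H)) for (j in seq_len(W)) {
    expected[1, c, i, j] <- x[1, c, i, j] * s_h[c, i] * s_w[c, j]
  }
  expect_equal(out, expected, tolerance = 1e-6)
})

test_that("coordinate attention rejects a vanishing reduced width", {
  expect_error(coordatt_layer(4, r = 8), "configuration error")
  expect_error(coord_att_params(4, r = 8), "configuration error")
})

test_that("batch permutation permutes outputs identically", {
  set.seed(26)
  m <- coordatt_layer(4, r = 2)
  x <- array(rnorm(5 * 4 * 6 * 6), c(5, 4, 6, 6))
  out <- module_forward(m, x)
  perm <- c(3, 1, 5, 2, 4)
  out_p <- module_forward(m, x[perm, , , , drop = FALSE])
  expect_equal(out_p, out[perm, , , , drop = FALSE], tolerance = 1e-12)
})

test_that("coordatt layer gradients agree with numerical differentiation", {
  set.seed(27)
  m <- coordatt_layer(4, r = 2)
  x <- array(rnorm(2 * 4 * 5 * 6), c(2, 4, 5, 6))
  expect_lt(grad_check_worst(m, x), 1e-5)
})

# ---- FCA -------------------------------------------------------------------

test_that("FCA with one identity-projected stage reduces to global pooling", {
  set.seed(28)
  x <- array(rnorm(3 * 5 * 4 * 4), c(3, 5, 4, 4))
  p <- fca_params(list(NULL), fusion = "sum")
  expect_equal(fca_forward(list(x), p), channel_global_pool(x))
})

test_that("FCA sum fusion is additive over identical stages", {
  set.seed(29)
  x <- array(rnorm(2 * 4 * 3 * 3), c(2, 4, 3, 3))
  p <- fca_params(list(NULL, NULL), fusion = "sum")
  expect_equal(fca_forward(list(x, x), p), 2 * channel_global_pool(x))
})

test_that("FCA matches a hand-composed pool+project+sum oracle", {
  set.seed(30)
  stages <- list(array(rnorm(2 * 3 * 4 * 4), c(2, 3, 4, 4)),
                 array(rnorm(2 * 5 * 2 * 2), c(2, 5, 2, 2)),
                 array(rnorm(2 * 4 * 3 * 3), c(2, 4, 3, 3)))
  projs <- list(matrix(rnorm(6 * 3), 6, 3), matrix(rnorm(6 * 5), 6, 5),
                matrix(rnorm(6 * 4), 6, 4))
  p <- fca_params(projs, fusion = "sum")
  out <- fca_forward(stages, p)
  expected <- matrix(0, 2, 6)
  for (i in 1:3) {
    g <- apply(stages[[i]], c(1, 2), mean)
    expected <- expected + g %*% t(projs[[i]])
  }
  expect_equal(out, expected, tolerance = 1e-6)

  pc <- fca_params(projs, fusion = "concat")
  expect_equal(ncol(fca_forward(stages, pc)), 18)
})

test_that("FCA reports width mismatches as configuration errors", {
  x <- array(0, c(1, 3, 2, 2))
  y <- array(0, c(1, 4, 2, 2))
  p <- fca_params(list(NULL, NULL), fusion = "sum")
  expect_error(fca_forward(list(x, y), p), "configuration error")
  p2 <- fca_params(list(matrix(0, 2, 4)), fusion = "sum")
  expect_error(fca_forward(list(x), p2), "configuration error")
})
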