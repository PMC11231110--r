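# Omni-dimensional dynamic convolution (ODConv).
#
# An ODConv layer holds n parallel kernels W_1..W_n. For every input
# sample, a light attention head produces four attention factors from the
# globally pooled feature vector:
#   alpha_s (k x k)   - kernel spatial positions
#   alpha_c (c_in)    - input channels
#   alpha_w (n)       - kernel index
#   alpha_f (c_out)   - output channels
# The sample is then convolved with the effective kernel
#   K = alpha_s (*) alpha_c (*) alpha_f (*) sum_i alpha_w[i] W_i,
# which makes the convolution input-conditioned while a single
# convolution's worth of multiply-accumulates is spent per sample.

# ---- domain types ------------------------------------------------------

#' Kernel bank of an ODConv layer
#'
#' The n parallel convolution kernels of one dynamic-convolution layer.
#'
#' @param kernels numeric array of shape `n x c_out x c_in x k x k`.
#' @param stride,padding convolution stride and zero padding.
#' @return An object of class `kernel_bank`.
#' @export
kernel_bank <- function(kernels, stride = 1L, padding = 0L) {
  d <- dim(kernels)
  if (length(d) != 5L) stop("kernels must be a 5-d array (n, c_out, c_in, k, k)")
  if (d[1] < 1L) stop("kernel bank needs n >= 1 kernels")
  if (d[4] != d[5]) stop("spatial kernel dims must be square")
  if (d[4] < 1L || d[4] %% 2L == 0L) stop("kernel size k must be odd and >= 1")
  if (stride < 1L) stop("stride must be a positive integer")
  if (padding < 0L) stop("padding must be non-negative")
  structure(list(kernels = kernels, stride = as.integer(stride),
                 padding = as.integer(padding),
                 n = d[1], c_out = d[2], c_in = d[3], k = d[4]),
            class = "kernel_bank")
}

# Squeezed width of the attention head.
squeezed_dim <- function(c_in, gamma) max(1L, as.integer(floor(c_in * gamma)))

#' Attention head of an ODConv layer
#'
#' A squeeze affine map `c_in -> max(1, floor(c_in * gamma))` followed (after
#' a rectifier) by four parallel affine heads whose output sizes match the
#' four kernel dimensions: `k*k` (spatial), `c_in` (input channel), `c_out`
#' (output channel) and `n` (kernel index). A sigmoid normalizes every head;
#' the kernel head can optionally use a softmax instead.
#'
#' @param c_in,c_out,k,n dimensions of the kernel bank the head modulates.
#' @param gamma squeeze reduction ratio in (0, 1].
#' @param kernel_attention `"sigmoid"` (default) or `"softmax"`
#'   normalization for the kernel-index head.
#' @param init `"he"` for random (RNG-dependent) weights or `"zero"`.
#' @return An object of class `omni_attention_head` with weight matrices
#'   `w_sq, w_s, w_c, w_f, w_w` and bias vectors `b_*`.
#' @export
omni_attention_head <- function(c_in, c_out, k, n, gamma = 1 / 16,
                                kernel_attention = c("sigmoid", "softmax"),
                                init = c("he", "zero")) {
  kernel_attention <- match.arg(kernel_attention)
  init <- match.arg(init)
  if (gamma <= 0 || gamma > 1) stop("gamma must lie in (0, 1]")
  s <- squeezed_dim(c_in, gamma)
  mk <- function(rows, cols, fan) {
    if (init == "zero") matrix(0, rows, cols) else matrix(he_init(c(rows, cols), fan), rows, cols)
  }
  structure(list(
    c_in = c_in, c_out = c_out, k = as.integer(k), n = as.integer(n),
    gamma = gamma, s = s, kernel_attention = kernel_attention,
    w_sq = mk(s, c_in, c_in), b_sq = numeric(s),
    w_s = mk(k * k, s, s), b_s = numeric(k * k),
    w_c = mk(c_in, s, s), b_c = numeric(c_in),
    w_f = mk(c_out, s, s), b_f = numeric(c_out),
    w_w = mk(n, s, s), b_w = numeric(n)
  ), class = "omni_attention_head")
}

#' Per-sample attention quadruple
#'
#' Container for the four ODConv attention factors of a batch; all values
#' lie strictly in (0, 1) when produced by sigmoid heads.
#'
#' @param alpha_s array `N x k x k` for a batch, or a `k x k` matrix for a
#'   single sample.
#' @param alpha_c matrix `N x c_in`, or a vector for a single sample.
#' @param alpha_f matrix `N x c_out`, or a vector for a single sample.
#' @param alpha_w matrix `N x n`, or a vector for a single sample.
#' @return An object of class `attention_quadruple`.
#' @export
attention_quadruple <- function(alpha_s, alpha_c, alpha_f, alpha_w) {
  if (!is.matrix(alpha_c)) alpha_c <- matrix(alpha_c, 1L)
  if (!is.matrix(alpha_f)) alpha_f <- matrix(alpha_f, 1L)
  if (!is.matrix(alpha_w)) alpha_w <- matrix(alpha_w, 1L)
  structure(list(alpha_s = alpha_s, alpha_c = alpha_c,
                 alpha_f = alpha_f, alpha_w = alpha_w,
                 n_sample = nrow(alpha_c)),
            class = "attention_quadruple")
}

#' Extract one sample's attention quadruple from a batch
#'
#' @param attn an [attention_quadruple()].
#' @param i sample index.
#' @return An `attention_quadruple` with `n_sample = 1`; `alpha_s` keeps its
#'   `k x k` shape.
#' @export
attn_sample <- function(attn, i) {
  attention_quadruple(
    alpha_s = array(attn$alpha_s[i, , ], dim(attn$alpha_s)[-1]),
    alpha_c = attn$alpha_c[i, , drop = FALSE],
    alpha_f = attn$alpha_f[i, , drop = FALSE],
    alpha_w = attn$alpha_w[i, , drop = FALSE])
}

# ---- attention computation ---------------------------------------------

# Shared straight-line pipeline on plain matrices; returns all
# intermediates so the layer backward can reuse it.
odconv_attention_pipeline <- function(x, head) {
  d <- dim(x)
  if (length(d) != 4L) stop("x must be a rank-4 array (N, c_in, H, W)")
  if (d[2] != head$c_in) {
    stop(sprintf("dimension error: input has %d channels but attention head expects %d",
                 d[2], head$c_in))
  }
  if (d[3] < 1L || d[4] < 1L) stop("dimension error: empty spatial extent")
  z <- {
    xm <- x
    dim(xm) <- c(d[1] * d[2], d[3] * d[4])
    matrix(rowMeans(xm), d[1], d[2])
  }
  h_pre <- sweep(tcrossprod(z, head$w_sq), 2L, head$b_sq, `+`)
  h <- relu(h_pre)
  pre <- list(
    s = sweep(tcrossprod(h, head$w_s), 2L, head$b_s, `+`),
    c = sweep(tcrossprod(h, head$w_c), 2L, head$b_c, `+`),
    f = sweep(tcrossprod(h, head$w_f), 2L, head$b_f, `+`),
    w = sweep(tcrossprod(h, head$w_w), 2L, head$b_w, `+`))
  alpha <- lapply(pre, sigmoid)
  if (head$kernel_attention == "softmax") {
    ew <- exp(sweep(pre$w, 1L, apply(pre$w, 1L, max)))
    alpha$w <- ew / rowSums(ew)
  }
  list(z = z, h = h, pre = pre, alpha = alpha, dims = d)
}

#' Compute the four ODConv attention factors for a batch
#'
#' Pipeline: channel-wise global average pooling, squeeze affine map,
#' rectifier, four parallel head affine maps, elementwise sigmoid (softmax
#' over the kernel head if the head was built with
#' `kernel_attention = "softmax"`).
#'
#' @param x rank-4 input array `N x c_in x H x W`.
#' @param head an [omni_attention_head()].
#' @return An [attention_quadruple()] holding one quadruple per sample.
#' @export
compute_attention <- function(x, head) {
  p <- odconv_attention_pipeline(x, head)
  N <- p$dims[1]; k <- head$k
  attention_quadruple(
    alpha_s = array(p$alpha$s, c(N, k, k)),
    alpha_c = p$alpha$c, alpha_f = p$alpha$f, alpha_w = p$alpha$w)
}

# ---- effective kernel and forward --------------------------------------

#' Aggregate a kernel bank into one effective kernel
#'
#' For a single sample's attention quadruple, returns
#' `sum_i alpha_w[i] * (W_i * alpha_s * alpha_c * alpha_f)` where `alpha_s`
#' broadcasts over channels, `alpha_c` over output channels and spatial
#' positions, and `alpha_f` over input channels and spatial positions.
#'
#' @param attn a single-sample [attention_quadruple()].
#' @param bank a [kernel_bank()].
#' @return Numeric array `c_out x c_in x k x k`.
#' @export
effective_kernel <- function(attn, bank) {
  if (attn$n_sample != 1L) {
    stop("effective_kernel expects a single-sample quadruple; use attn_sample()")
  }
  if (length(attn$alpha_c) != bank$c_in || length(attn$alpha_f) != bank$c_out ||
      length(attn$alpha_w) != bank$n || length(attn$alpha_s) != bank$k^2) {
    stop("dimension error: attention quadruple does not match kernel bank")
  }
  km <- matrix(bank$kernels, bank$n, bank$c_out * bank$c_in * bank$k^2)
  wbar <- colSums(km * as.numeric(attn$alpha_w))
  kk <- array(wbar, c(bank$c_out, bank$c_in, bank$k, bank$k))
  kk <- kk * as.numeric(attn$alpha_f)                       # over (c,u,v)
  kk <- kk * rep(as.numeric(attn$alpha_c), each = bank$c_out)  # over (u,v)
  kk * rep(as.numeric(attn$alpha_s), each = bank$c_out * bank$c_in)
}

# Core per-sample dynamic convolution. alpha_c and alpha_f are applied to
# the input/output feature maps (mathematically identical to folding them
# into the effective kernel); alpha_s and alpha_w are folded into the
# per-sample kernel. Returns intermediates when cache = TRUE.
odconv_core_forward <- function(x, kernels, attn_mats, stride, pad, cache = FALSE) {
  d <- dim(x)
  N <- d[1]
  bank_d <- dim(kernels)
  n <- bank_d[1]; c_out <- bank_d[2]; c_in <- bank_d[3]; k <- bank_d[4]
  xm <- bmul_nc(x, attn_mats$c)
  info <- im2col(xm, k, stride, pad, sample_blocks = TRUE)
  Ho <- info$Ho; Wo <- info$Wo
  kbm <- matrix(kernels, n, c_out * c_in * k * k)
  wbar <- attn_mats$w %*% kbm                       # N x (c_out*c_in*k*k)
  spat_rep <- rep(seq_len(k * k), each = c_out * c_in)
  om <- matrix(0, Ho * Wo * N, c_out)
  kmats <- if (cache) vector("list", N) else NULL
  blk <- Ho * Wo
  for (i in seq_len(N)) {
    ki <- array(wbar[i, ] * attn_mats$s[i, spat_rep], c(c_out, c_in, k, k))
    kmat <- kernel_to_mat(ki)
    rows <- (i - 1L) * blk + seq_len(blk)
    om[rows, ] <- info$mat[rows, , drop = FALSE] %*% kmat
    if (cache) kmats[[i]] <- kmat
  }
  y0 <- aperm(array(om, c(Ho, Wo, N, c_out)), c(3L, 4L, 1L, 2L))
  y <- bmul_nc(y0, attn_mats$f)
  if (cache) {
    list(y = y, y0 = y0, xm = xm, info = info, wbar = wbar, kmats = kmats,
         spat_rep = spat_rep, kbm = kbm)
  } else {
    list(y = y)
  }
}

#' Omni-dimensional dynamic convolution forward pass (functional form)
#'
#' Computes each sample's attention quadruple from `head`, materializes the
#' sample's effective kernel from `bank`, and convolves. Output spatial
#' size follows standard convolution arithmetic; no convolution bias.
#'
#' @param x rank-4 input array `N x c_in x H x W`.
#' @param bank a [kernel_bank()].
#' @param head an [omni_attention_head()] matching the bank's dimensions.
#' @return Rank-4 output array `N x c_out x Ho x Wo`.
#' @export
odconv_forward <- function(x, bank, head) {
  if (dim(x)[2] != bank$c_in) {
    stop(sprintf("dimension error: input has %d channels, kernel bank expects %d",
                 dim(x)[2], bank$c_in))
  }
  p <- odconv_attention_pipeline(x, head)
  odconv_core_forward(x, bank$kernels, p$alpha, bank$stride, bank$padding)$y
}

#' Closed-form trainable-parameter count of one ODConv layer
#'
#' Kernels (`n * c_out * c_in * k^2`, no bias) plus the squeeze affine and
#' the four head affines, all with bias.
#'
#' @param bank a [kernel_bank()].
#' @param head an [omni_attention_head()].
#' @return Integer parameter count.
#' @export
odconv_param_count <- function(bank, head) {
  s <- head$s
  kernels <- bank$n * bank$c_out * bank$c_in * bank$k^2
  squeeze <- s * (bank$c_in + 1L)
  heads <- (bank$k^2 + bank$c_in + bank$c_out + bank$n) * (s + 1L)
  as.integer(kernels + squeeze + heads)
}

# ---- trainable layer ---------------------------------------------------

#' Trainable ODConv layer
#'
#' @param c_in,c_out channel counts.
#' @param k kernel size (odd).
#' @param stride,pad convolution stride and zero padding.
#' @param n number of parallel kernels.
#' @param gamma attention squeeze ratio in (0, 1].
#' @param kernel_attention `"sigmoid"` or `"softmax"` for the kernel head.
#' @return A module.
#' @export
odconv_layer <- function(c_in, c_out, k = 3L, stride = 1L, pad = 1L,
                         n = 4L, gamma = 1 / 16,
                         kernel_attention = c("sigmoid", "softmax")) {
  kernel_attention <- match.arg(kernel_attention)
  s <- squeezed_dim(c_in, gamma)
  params <- list(
    kernels = he_init(c(n, c_out, c_in, k, k), fan_in = c_in * k * k),
    w_sq = matrix(he_init(c(s, c_in), c_in), s, c_in), b_sq = numeric(s),
    w_s = matrix(he_init(c(k * k, s), s), k * k, s), b_s = numeric(k * k),
    w_c = matrix(he_init(c(c_in, s), s), c_in, s), b_c = numeric(c_in),
    w_f = matrix(he_init(c(c_out, s), s), c_out, s), b_f = numeric(c_out),
    w_w = matrix(he_init(c(n, s), s), n, s), b_w = numeric(n))
  new_module("odconv_layer",
             c_in = c_in, c_out = c_out, k = as.integer(k),
             stride = as.integer(stride), pad = as.integer(pad),
             n = as.integer(n), gamma = gamma, s = s,
             kernel_attention = kernel_attention, params = params)
}

# Assemble an omni_attention_head view over the layer's parameters.
odconv_layer_head <- function(m) {
  structure(list(
    c_in = m$c_in, c_out = m$c_out, k = m$k, n = m$n, gamma = m$gamma,
    s = m$s, kernel_attention = m$kernel_attention,
    w_sq = m$params$w_sq, b_sq = m$params$b_sq,
    w_s = m$params$w_s, b_s = m$params$b_s,
    w_c = m$params$w_c, b_c = m$params$b_c,
    w_f = m$params$w_f, b_f = m$params$b_f,
    w_w = m$params$w_w, b_w = m$params$b_w), class = "omni_attention_head")
}

#' Kernel-bank view over a trainable ODConv layer
#' @param m an [odconv_layer()].
#' @return The layer's [kernel_bank()].
#' @export
odconv_layer_bank <- function(m) {
  kernel_bank(m$params$kernels, stride = m$stride, padding = m$pad)
}

#' @export
module_forward.odconv_layer <- function(m, x, training = FALSE) {
  p <- odconv_attention_pipeline(x, odconv_layer_head(m))
  r <- odconv_core_forward(x, m$params$kernels, p$alpha, m$stride, m$pad,
                           cache = training)
  if (training) m$cache <- list(x = x, p = p, core = r)
  r$y
}

#' @export
module_backward.odconv_layer <- function(m, dout) {
  cache <- m$cache
  p <- cache$p
  core <- cache$core
  x <- cache$x
  d <- dim(x)
  N <- d[1]; H <- d[3]; W <- d[4]
  c_out <- m$c_out; c_in <- m$c_in; k <- m$k; n <- m$n
  alpha <- p$alpha
  info <- core$info
  Ho <- info$Ho; Wo <- info$Wo
  blk <- Ho * Wo
  M <- c_out * c_in * k * k

  # output-channel gate
  dalpha_f <- rsum_spatial(dout * core$y0)
  dy0 <- bmul_nc(dout, alpha$f)

  # per-sample convolution backward
  dom <- matrix(aperm(dy0, c(3L, 4L, 1L, 2L)), blk * N, c_out)
  dxmat <- matrix(0, blk * N, c_in * k * k)
  dK <- matrix(0, N, M)   # grad of each sample's (spatially modulated) kernel
  for (i in seq_len(N)) {
    rows <- (i - 1L) * blk + seq_len(blk)
    xb <- info$mat[rows, , drop = FALSE]
    db <- dom[rows, , drop = FALSE]
    dkmat <- crossprod(xb, db)                  # (c_in*k*k) x c_out
    dK[i, ] <- c(mat_to_kernel(dkmat, c_out, c_in, k))
    dxmat[rows, ] <- tcrossprod(db, core$kmats[[i]])
  }
  dxm <- col2im(dxmat, info)

  # spatial gate and kernel mixture
  spat_rep <- core$spat_rep
  dwbar <- dK * alpha$s[, spat_rep, drop = FALSE]            # N x M
  # dalpha_s[i, uv] = sum_{o,c} dK[i, (o,c,uv)] * wbar[i, (o,c,uv)]
  prod_s <- dK * core$wbar
  dim(prod_s) <- c(N, c_out * c_in, k * k)
  dalpha_s <- apply(prod_s, c(1L, 3L), sum)
  dalpha_w <- tcrossprod(dwbar, core$kbm)                    # N x n
  m$grads$kernels <- m$grads$kernels +
    array(crossprod(alpha$w, dwbar), c(n, c_out, c_in, k, k))

  # input-channel gate
  dalpha_c <- rsum_spatial(dxm * x)
  dx <- bmul_nc(dxm, alpha$c)

  # attention head backward
  dpre <- list(
    s = dalpha_s * alpha$s * (1 - alpha$s),
    c = dalpha_c * alpha$c * (1 - alpha$c),
    f = dalpha_f * alpha$f * (1 - alpha$f))
  dpre$w <- if (m$kernel_attention == "softmax") {
    alpha$w * (dalpha_w - rowSums(dalpha_w * alpha$w))
  } else {
    dalpha_w * alpha$w * (1 - alpha$w)
  }
  heads <- c("s", "c", "f", "w")
  dh <- matrix(0, N, m$s)
  for (hd in heads) {
    wname <- paste0("w_", hd); bname <- paste0("b_", hd)
    m$grads[[wname]] <- m$grads[[wname]] + crossprod(dpre[[hd]], p$h)
    m$grads[[bname]] <- m$grads[[bname]] + colSums(dpre[[hd]])
    dh <- dh + dpre[[hd]] %*% m$params[[wname]]
  }
  dh_pre <- dh * (p$h > 0)
  m$grads$w_sq <- m$grads$w_sq + crossprod(dh_pre, p$z)
  m$grads$b_sq <- m$grads$b_sq + colSums(dh_pre)
  dz <- dh_pre %*% m$params$w_sq
  dx + array(c(dz) / (H * W), d)
}
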