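# Coordinate attention (CA).
#
# Instead of collapsing the whole spatial extent to one scalar per channel
# (SE-style), CA pools the input separately along height and width. The two
# directional profiles are concatenated, squeezed through a shared 1x1
# reduce transform (c -> floor(c/r), optionally batch-normalized), split
# back, expanded per direction to c channels, and passed through a sigmoid.
# The resulting gate maps s_h (N,C,H,1) and s_w (N,C,1,W) reweight the
# input multiplicatively, so positional information along each axis
# survives the channel gating.

#' Channel-wise global average pooling
#'
#' `z[n, c] = mean over (i, j) of x[n, c, i, j]`.
#'
#' @param x rank-4 array `N x C x H x W`.
#' @return `N x C` matrix.
#' @export
channel_global_pool <- function(x) {
  d <- dim(x)
  if (length(d) != 4L) stop("x must be a rank-4 array (N, C, H, W)")
  if (d[3] < 1L || d[4] < 1L) stop("dimension error: empty spatial extent")
  dim(x) <- c(d[1] * d[2], d[3] * d[4])
  matrix(rowMeans(x), d[1], d[2])
}

#' Directional average pools
#'
#' Averages over the width axis to a height profile and over the height
#' axis to a width profile. The mean of either profile equals the global
#' channel mean.
#'
#' @param x rank-4 array `N x C x H x W`.
#' @return List with `h` (`N x C x H x 1` array) and `w` (`N x C x 1 x W`).
#' @export
directional_pools <- function(x) {
  d <- dim(x)
  if (length(d) != 4L) stop("x must be a rank-4 array (N, C, H, W)")
  if (d[3] < 1L || d[4] < 1L) stop("dimension error: empty spatial extent")
  hprof <- mean_over_w(x)   # (N, C, H)
  wprof <- mean_over_h(x)   # (N, C, W)
  list(h = array(hprof, c(d[1], d[2], d[3], 1L)),
       w = array(wprof, c(d[1], d[2], 1L, d[4])))
}

#' Coordinate-attention parameters
#'
#' Weights of one CA block: a shared 1x1 reduce convolution
#' `c -> floor(c/r)` and two per-direction 1x1 expand convolutions back to
#' `c`, all with bias. Acting on 1-wide profiles, the 1x1 convolutions are
#' affine maps over the channel dimension.
#'
#' @param C channel count of the gated feature map.
#' @param r channel-reduction parameter (positive integer).
#' @param w_reduce,b_reduce reduce transform, `floor(C/r) x C` and length
#'   `floor(C/r)`; zero-initialized when omitted.
#' @param w_h,b_h,w_w,b_w expand transforms, `C x floor(C/r)` and length `C`.
#' @return An object of class `coord_att_params`.
#' @export
coord_att_params <- function(C, r = 8L, w_reduce = NULL, b_reduce = NULL,
                             w_h = NULL, b_h = NULL, w_w = NULL, b_w = NULL) {
  cr <- as.integer(floor(C / r))
  if (cr < 1L) stop(sprintf("configuration error: floor(C/r) = floor(%d/%d) is zero", C, r))
  zm <- function(rr, cc) matrix(0, rr, cc)
  structure(list(
    C = C, r = as.integer(r), c_red = cr,
    w_reduce = if (is.null(w_reduce)) zm(cr, C) else w_reduce,
    b_reduce = if (is.null(b_reduce)) numeric(cr) else b_reduce,
    w_h = if (is.null(w_h)) zm(C, cr) else w_h,
    b_h = if (is.null(b_h)) numeric(C) else b_h,
    w_w = if (is.null(w_w)) zm(C, cr) else w_w,
    b_w = if (is.null(b_w)) numeric(C) else b_w), class = "coord_att_params")
}

#' Coordinate-attention forward pass (functional form)
#'
#' Directional pools -> concatenate along the spatial axis -> reduce
#' transform -> rectifier -> split -> per-direction expand transform ->
#' sigmoid -> gate maps `s_h`, `s_w`; output is `x * s_h * s_w`
#' (broadcast), so the output shape equals the input shape. This
#' functional form has no normalization step after the reduce transform;
#' the trainable [coordatt_layer()] adds one behind a flag.
#'
#' @param x rank-4 array `N x C x H x W`.
#' @param p a [coord_att_params()].
#' @return Array with the same shape as `x`.
#' @export
coordatt_forward <- function(x, p) {
  d <- dim(x)
  if (d[2] != p$C) {
    stop(sprintf("dimension error: input has %d channels but CA params expect %d",
                 d[2], p$C))
  }
  N <- d[1]; C <- d[2]; H <- d[3]; W <- d[4]
  hprof <- mean_over_w(x)                       # (N, C, H)
  wprof <- mean_over_h(x)                       # (N, C, W)
  u <- array(0, c(N, C, H + W))
  u[, , seq_len(H)] <- hprof
  u[, , H + seq_len(W)] <- wprof
  um <- matrix(aperm(u, c(1L, 3L, 2L)), N * (H + W), C)
  v <- relu(sweep(tcrossprod(um, p$w_reduce), 2L, p$b_reduce, `+`))
  va <- array(v, c(N, H + W, p$c_red))
  vh <- matrix(va[, seq_len(H), , drop = FALSE], N * H, p$c_red)
  vw <- matrix(va[, H + seq_len(W), , drop = FALSE], N * W, p$c_red)
  s_h <- aperm(array(sigmoid(sweep(tcrossprod(vh, p$w_h), 2L, p$b_h, `+`)),
                     c(N, H, C)), c(1L, 3L, 2L))   # (N, C, H)
  s_w <- aperm(array(sigmoid(sweep(tcrossprod(vw, p$w_w), 2L, p$b_w, `+`)),
                     c(N, W, C)), c(1L, 3L, 2L))   # (N, C, W)
  bmul_ncw(bmul_nch(x, s_h), s_w)
}

# ---- trainable layer ---------------------------------------------------

#' Trainable coordinate-attention block
#'
#' @param C channel count.
#' @param r channel-reduction parameter.
#' @param bn_after_reduce apply batch normalization between the reduce
#'   transform and the rectifier (default on).
#' @return A module; output shape equals input shape.
#' @export
coordatt_layer <- function(C, r = 8L, bn_after_reduce = TRUE) {
  cr <- as.integer(floor(C / r))
  if (cr < 1L) stop(sprintf("configuration error: floor(C/r) = floor(%d/%d) is zero", C, r))
  params <- list(
    w_reduce = matrix(he_init(c(cr, C), C), cr, C), b_reduce = numeric(cr),
    w_h = matrix(he_init(c(C, cr), cr), C, cr), b_h = numeric(C),
    w_w = matrix(he_init(c(C, cr), cr), C, cr), b_w = numeric(C))
  children <- list()
  if (bn_after_reduce) children$bn <- batchnorm1d_layer(cr)
  new_module("coordatt_layer", C = C, r = as.integer(r), c_red = cr,
             bn_after_reduce = bn_after_reduce,
             params = params, children = children)
}

#' @export
module_forward.coordatt_layer <- function(m, x, training = FALSE) {
  d <- dim(x)
  if (d[2] != m$C) {
    stop(sprintf("dimension error: input has %d channels but CA layer expects %d",
                 d[2], m$C))
  }
  N <- d[1]; C <- d[2]; H <- d[3]; W <- d[4]
  hprof <- mean_over_w(x)
  wprof <- mean_over_h(x)
  u <- array(0, c(N, C, H + W))
  u[, , seq_len(H)] <- hprof
  u[, , H + seq_len(W)] <- wprof
  um <- matrix(aperm(u, c(1L, 3L, 2L)), N * (H + W), C)
  v_pre <- sweep(tcrossprod(um, m$params$w_reduce), 2L, m$params$b_reduce, `+`)
  v_bn <- if (m$bn_after_reduce) {
    module_forward(m$children$bn, v_pre, training)
  } else v_pre
  v <- relu(v_bn)
  va <- array(v, c(N, H + W, m$c_red))
  vh <- matrix(va[, seq_len(H), , drop = FALSE], N * H, m$c_red)
  vw <- matrix(va[, H + seq_len(W), , drop = FALSE], N * W, m$c_red)
  sh_flat <- sigmoid(sweep(tcrossprod(vh, m$params$w_h), 2L, m$params$b_h, `+`))
  sw_flat <- sigmoid(sweep(tcrossprod(vw, m$params$w_w), 2L, m$params$b_w, `+`))
  s_h <- aperm(array(sh_flat, c(N, H, C)), c(1L, 3L, 2L))
  s_w <- aperm(array(sw_flat, c(N, W, C)), c(1L, 3L, 2L))
  out <- bmul_ncw(bmul_nch(x, s_h), s_w)
  if (training) {
    m$cache <- list(x = x, dims = d, um = um, v_bn_mask = v_bn > 0,
                    vh = vh, vw = vw, sh_flat = sh_flat, sw_flat = sw_flat,
                    s_h = s_h, s_w = s_w)
  }
  out
}

#' @export
module_backward.coordatt_layer <- function(m, dout) {
  cc <- m$cache
  d <- cc$dims
  N <- d[1]; C <- d[2]; H <- d[3]; W <- d[4]
  x <- cc$x

  # gate gradients
  t1 <- dout * x
  ds_h <- sum_over_w(bmul_ncw(t1, cc$s_w))            # (N, C, H)
  ds_w <- sum_over_h(bmul_nch(t1, cc$s_h))            # (N, C, W)
  dx <- bmul_ncw(bmul_nch(dout, cc$s_h), cc$s_w)

  # sigmoid + expand transforms
  dsh_flat <- matrix(aperm(ds_h, c(1L, 3L, 2L)), N * H, C) *
    cc$sh_flat * (1 - cc$sh_flat)
  dsw_flat <- matrix(aperm(ds_w, c(1L, 3L, 2L)), N * W, C) *
    cc$sw_flat * (1 - cc$sw_flat)
  m$grads$w_h <- m$grads$w_h + crossprod(dsh_flat, cc$vh)
  m$grads$b_h <- m$grads$b_h + colSums(dsh_flat)
  m$grads$w_w <- m$grads$w_w + crossprod(dsw_flat, cc$vw)
  m$grads$b_w <- m$grads$b_w + colSums(dsw_flat)
  dvh <- dsh_flat %*% m$params$w_h                    # (N*H, c_red)
  dvw <- dsw_flat %*% m$params$w_w                    # (N*W, c_red)

  # reassemble concatenated profile gradient
  dva <- array(0, c(N, H + W, m$c_red))
  dva[, seq_len(H), ] <- array(dvh, c(N, H, m$c_red))
  dva[, H + seq_len(W), ] <- array(dvw, c(N, W, m$c_red))
  dv <- matrix(dva, N * (H + W), m$c_red)

  # rectifier, optional batch norm, reduce transform
  dv_bn <- dv * cc$v_bn_mask
  dv_pre <- if (m$bn_after_reduce) {
    module_backward(m$children$bn, dv_bn)
  } else dv_bn
  m$grads$w_reduce <- m$grads$w_reduce + crossprod(dv_pre, cc$um)
  m$grads$b_reduce <- m$grads$b_reduce + colSums(dv_pre)
  dum <- dv_pre %*% m$params$w_reduce                 # (N*(H+W), C)

  # directional-pool backward
  du <- aperm(array(dum, c(N, H + W, C)), c(1L, 3L, 2L))
  dhprof <- array(du[, , seq_len(H)], c(N, C, H))
  dwprof <- array(du[, , H + seq_len(W)], c(N, C, W))
  dx <- dx + array(c(dhprof) / W, d)                  # broadcast over W
  dx + expand_ncw(dwprof, H) / H
}
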