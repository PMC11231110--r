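# Minimal trainable-module framework. A module is an environment holding
# `params` (named list of arrays), `grads` (same shapes, accumulated by
# backward), optional non-trainable `buffers` (e.g. batch-norm running
# stats), and `children` (named list of sub-modules). Forward passes cache
# whatever the matching backward pass needs.

new_module <- function(cls, ...) {
  m <- new.env(parent = emptyenv())
  fields <- list(...)
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = m)
  if (is.null(m$params)) m$params <- list()
  if (is.null(m$children)) m$children <- list()
  m$grads <- lapply(m$params, function(p) array(0, dim(as.array(p))))
  class(m) <- c(cls, "odf_module")
  m
}

#' Forward pass through a module
#'
#' @param m a module built by one of the layer or network constructors.
#' @param x input array (layout documented per layer).
#' @param training logical; `TRUE` uses batch statistics in normalization
#'   layers and caches intermediates for [module_backward()].
#' @return The module output.
#' @export
module_forward <- function(m, x, training = FALSE) UseMethod("module_forward")

#' Backward pass through a module
#'
#' Accumulates parameter gradients into the module and returns the
#' gradient with respect to the module input. Must follow a forward pass
#' with `training = TRUE`.
#'
#' @param m a module.
#' @param dout gradient of the loss with respect to the module output.
#' @return Gradient with respect to the module input.
#' @export
module_backward <- function(m, dout) UseMethod("module_backward")

#' @export
module_forward.default <- function(m, x, training = FALSE) {
  stop("no forward method for class ", paste(class(m), collapse = "/"))
}
#' @export
module_backward.default <- function(m, dout) {
  stop("no backward method for class ", paste(class(m), collapse = "/"))
}

# Flat named list of every parameter array in a module tree.
#' Collect all trainable parameter arrays of a model
#'
#' @param m a module.
#' @param prefix name prefix used during recursion.
#' @return Named list of parameter arrays; names encode the module path.
#' @export
module_param_list <- function(m, prefix = "") {
  out <- list()
  if (length(m$params)) {
    nms <- paste0(prefix, names(m$params))
    out <- stats::setNames(m$params, nms)
  }
  for (nm in names(m$children)) {
    out <- c(out, module_param_list(m$children[[nm]], paste0(prefix, nm, ".")))
  }
  out
}

# Walk a module tree, applying f(module) to every node.
walk_modules <- function(m, f) {
  f(m)
  for (ch in m$children) walk_modules(ch, f)
  invisible(NULL)
}

#' Zero all accumulated gradients in a module tree
#' @param m a module.
#' @export
zero_grads <- function(m) {
  walk_modules(m, function(mod) {
    for (nm in names(mod$params)) {
      mod$grads[[nm]][] <- 0
    }
  })
  invisible(m)
}

# ---- static 2-d convolution -------------------------------------------

#' Static 2-d convolution layer
#'
#' Plain (input-independent) convolution, `c_in -> c_out` with a `k x k`
#' kernel. Used for the network stem, shortcut projections and the
#' ResNet baselines.
#'
#' @param c_in,c_out channel counts.
#' @param k kernel size (odd).
#' @param stride,pad convolution stride and zero padding.
#' @param bias include an additive per-output-channel bias.
#' @return A module.
#' @export
conv_layer <- function(c_in, c_out, k, stride = 1L, pad = 0L, bias = FALSE) {
  params <- list(weight = he_init(c(c_out, c_in, k, k), fan_in = c_in * k * k))
  if (bias) params$bias <- numeric(c_out)
  new_module("conv_layer",
             c_in = c_in, c_out = c_out, k = as.integer(k),
             stride = as.integer(stride), pad = as.integer(pad),
             use_bias = bias, params = params)
}

#' @export
module_forward.conv_layer <- function(m, x, training = FALSE) {
  info <- im2col(x, m$k, m$stride, m$pad)
  wmat <- kernel_to_mat(m$params$weight)
  om <- info$mat %*% wmat
  out <- aperm(array(om, c(info$N, info$Ho, info$Wo, m$c_out)), c(1L, 4L, 2L, 3L))
  if (m$use_bias) out <- out + rep(m$params$bias, each = info$N)
  if (training) m$cache <- list(info = info, wmat = wmat)
  out
}

#' @export
module_backward.conv_layer <- function(m, dout) {
  info <- m$cache$info
  dom <- matrix(aperm(dout, c(1L, 3L, 4L, 2L)), info$N * info$Ho * info$Wo, m$c_out)
  dwmat <- crossprod(info$mat, dom)
  m$grads$weight <- m$grads$weight + mat_to_kernel(dwmat, m$c_out, m$c_in, m$k)
  if (m$use_bias) m$grads$bias <- m$grads$bias + colSums(dom)
  dxmat <- tcrossprod(dom, m$cache$wmat)
  col2im(dxmat, info)
}

# ---- batch normalization ----------------------------------------------

# Shared core: normalize the columns of a (samples x channels) matrix.
bn_mat_forward <- function(xm, gamma, beta, rmean, rvar, training, momentum, eps) {
  if (training) {
    mu <- colMeans(xm)
    xc <- sweep(xm, 2L, mu)
    v <- colMeans(xc * xc)
    inv_sd <- 1 / sqrt(v + eps)
    xhat <- sweep(xc, 2L, inv_sd, `*`)
    mcount <- nrow(xm)
    unbias <- if (mcount > 1L) mcount / (mcount - 1L) else 1
    new_rmean <- (1 - momentum) * rmean + momentum * mu
    new_rvar <- (1 - momentum) * rvar + momentum * v * unbias
    out <- sweep(sweep(xhat, 2L, gamma, `*`), 2L, beta, `+`)
    list(out = out, xhat = xhat, inv_sd = inv_sd,
         rmean = new_rmean, rvar = new_rvar)
  } else {
    inv_sd <- 1 / sqrt(rvar + eps)
    xhat <- sweep(sweep(xm, 2L, rmean), 2L, inv_sd, `*`)
    out <- sweep(sweep(xhat, 2L, gamma, `*`), 2L, beta, `+`)
    list(out = out)
  }
}

bn_mat_backward <- function(dout, xhat, inv_sd, gamma) {
  mcount <- nrow(dout)
  dgamma <- colSums(dout * xhat)
  dbeta <- colSums(dout)
  dxhat <- sweep(dout, 2L, gamma, `*`)
  t1 <- sweep(dxhat, 2L, colSums(dxhat) / mcount)
  t2 <- sweep(xhat, 2L, colSums(dxhat * xhat) / mcount, `*`)
  dx <- sweep(t1 - t2, 2L, inv_sd, `*`)
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

#' Batch-normalization layer over channels of an (N,C,H,W) array
#'
#' @param C channel count.
#' @param momentum running-statistics update rate.
#' @param eps variance floor.
#' @return A module with trainable scale/shift and running-statistics
#'   buffers (buffers are not counted as parameters).
#' @export
batchnorm_layer <- function(C, momentum = 0.1, eps = 1e-5) {
  new_module("batchnorm_layer",
             C = C, momentum = momentum, eps = eps,
             params = list(gamma = rep(1, C), beta = numeric(C)),
             buffers = list(running_mean = numeric(C), running_var = rep(1, C)))
}

# Accumulate exact first/second moments during a statistics pass
# (see recalibrate_bn_stats()).
bn_accumulate <- function(m, xm) {
  if (is.null(m$stats_accum)) return(invisible(NULL))
  m$stats_accum$sum <- m$stats_accum$sum + colSums(xm)
  m$stats_accum$sumsq <- m$stats_accum$sumsq + colSums(xm * xm)
  m$stats_accum$n <- m$stats_accum$n + nrow(xm)
  invisible(NULL)
}

#' @export
module_forward.batchnorm_layer <- function(m, x, training = FALSE) {
  d <- dim(x)
  xm <- matrix(aperm(x, c(1L, 3L, 4L, 2L)), d[1] * d[3] * d[4], d[2])
  if (training) bn_accumulate(m, xm)
  r <- bn_mat_forward(xm, m$params$gamma, m$params$beta,
                      m$buffers$running_mean, m$buffers$running_var,
                      training, m$momentum, m$eps)
  if (training) {
    m$buffers$running_mean <- r$rmean
    m$buffers$running_var <- r$rvar
    m$cache <- list(xhat = r$xhat, inv_sd = r$inv_sd, dims = d)
  }
  aperm(array(r$out, c(d[1], d[3], d[4], d[2])), c(1L, 4L, 2L, 3L))
}

#' @export
module_backward.batchnorm_layer <- function(m, dout) {
  d <- m$cache$dims
  dm <- matrix(aperm(dout, c(1L, 3L, 4L, 2L)), d[1] * d[3] * d[4], d[2])
  r <- bn_mat_backward(dm, m$cache$xhat, m$cache$inv_sd, m$params$gamma)
  m$grads$gamma <- m$grads$gamma + r$dgamma
  m$grads$beta <- m$grads$beta + r$dbeta
  aperm(array(r$dx, c(d[1], d[3], d[4], d[2])), c(1L, 4L, 2L, 3L))
}

# 1-d variant operating on a (samples x channels) matrix; used inside the
# coordinate-attention reduce transform.
batchnorm1d_layer <- function(C, momentum = 0.1, eps = 1e-5) {
  m <- batchnorm_layer(C, momentum, eps)
  class(m) <- c("batchnorm1d_layer", "odf_module")
  m
}

#' @export
module_forward.batchnorm1d_layer <- function(m, x, training = FALSE) {
  if (training) bn_accumulate(m, x)
  r <- bn_mat_forward(x, m$params$gamma, m$params$beta,
                      m$buffers$running_mean, m$buffers$running_var,
                      training, m$momentum, m$eps)
  if (training) {
    m$buffers$running_mean <- r$rmean
    m$buffers$running_var <- r$rvar
    m$cache <- list(xhat = r$xhat, inv_sd = r$inv_sd)
  }
  r$out
}

#' @export
module_backward.batchnorm1d_layer <- function(m, dout) {
  r <- bn_mat_backward(dout, m$cache$xhat, m$cache$inv_sd, m$params$gamma)
  m$grads$gamma <- m$grads$gamma + r$dgamma
  m$grads$beta <- m$grads$beta + r$dbeta
  r$dx
}

# ---- ReLU --------------------------------------------------------------

#' Rectified-linear activation layer
#' @return A parameter-free module.
#' @export
relu_layer <- function() new_module("relu_layer")

#' @export
module_forward.relu_layer <- function(m, x, training = FALSE) {
  out <- relu(x)
  if (training) m$cache <- list(mask = x > 0)
  out
}

#' @export
module_backward.relu_layer <- function(m, dout) dout * m$cache$mask

# ---- max pooling -------------------------------------------------------

#' Max-pooling layer
#'
#' @param k window size.
#' @param stride window step.
#' @param pad zero padding (padded cells never win the max).
#' @return A parameter-free module.
#' @export
maxpool_layer <- function(k = 3L, stride = 2L, pad = 1L) {
  new_module("maxpool_layer", k = as.integer(k), stride = as.integer(stride),
             pad = as.integer(pad))
}

#' @export
module_forward.maxpool_layer <- function(m, x, training = FALSE) {
  d <- dim(x)
  N <- d[1]; C <- d[2]; H <- d[3]; W <- d[4]
  k <- m$k; stride <- m$stride; pad <- m$pad
  Ho <- conv_out_size(H, k, stride, pad)
  Wo <- conv_out_size(W, k, stride, pad)
  xp <- pad4d(x, pad, value = -Inf)
  best <- array(-Inf, c(N, C, Ho, Wo))
  amax <- array(0L, c(N, C, Ho, Wo))
  off <- 0L
  for (u in seq_len(k)) {
    rows <- (seq_len(Ho) - 1L) * stride + u
    for (v in seq_len(k)) {
      off <- off + 1L
      ccols <- (seq_len(Wo) - 1L) * stride + v
      cand <- xp[, , rows, ccols, drop = FALSE]
      dim(cand) <- c(N, C, Ho, Wo)
      upd <- cand > best
      best[upd] <- cand[upd]
      amax[upd] <- off
    }
  }
  if (training) m$cache <- list(amax = amax, dims = d, Ho = Ho, Wo = Wo)
  best
}

#' @export
module_backward.maxpool_layer <- function(m, dout) {
  d <- m$cache$dims
  k <- m$k; stride <- m$stride; pad <- m$pad
  Ho <- m$cache$Ho; Wo <- m$cache$Wo
  dxp <- array(0, c(d[1], d[2], d[3] + 2L * pad, d[4] + 2L * pad))
  off <- 0L
  for (u in seq_len(k)) {
    rows <- (seq_len(Ho) - 1L) * stride + u
    for (v in seq_len(k)) {
      off <- off + 1L
      ccols <- (seq_len(Wo) - 1L) * stride + v
      contrib <- dout * (m$cache$amax == off)
      dxp[, , rows, ccols] <- dxp[, , rows, ccols, drop = FALSE] + contrib
    }
  }
  if (pad > 0L) dxp[, , pad + seq_len(d[3]), pad + seq_len(d[4]), drop = FALSE] else dxp
}

# ---- global average pooling -------------------------------------------

#' Global average-pooling layer, (N,C,H,W) -> (N,C)
#' @return A parameter-free module.
#' @export
gap_layer <- function() new_module("gap_layer")

#' @export
module_forward.gap_layer <- function(m, x, training = FALSE) {
  d <- dim(x)
  if (training) m$cache <- list(dims = d)
  dim(x) <- c(d[1] * d[2], d[3] * d[4])
  matrix(rowMeans(x), d[1], d[2])
}

#' @export
module_backward.gap_layer <- function(m, dout) {
  d <- m$cache$dims
  array(c(dout) / (d[3] * d[4]), d)
}

# ---- affine / linear ---------------------------------------------------

#' Affine (fully connected) layer on (N, in) matrices
#'
#' @param d_in,d_out input and output widths.
#' @param bias include an additive bias.
#' @return A module.
#' @export
linear_layer <- function(d_in, d_out, bias = TRUE) {
  params <- list(weight = he_init(c(d_out, d_in), fan_in = d_in))
  if (bias) params$bias <- numeric(d_out)
  new_module("linear_layer", d_in = d_in, d_out = d_out, use_bias = bias,
             params = params)
}

#' @export
module_forward.linear_layer <- function(m, x, training = FALSE) {
  out <- tcrossprod(x, m$params$weight)
  if (m$use_bias) out <- sweep(out, 2L, m$params$bias, `+`)
  if (training) m$cache <- list(x = x)
  out
}

#' @export
module_backward.linear_layer <- function(m, dout) {
  m$grads$weight <- m$grads$weight + crossprod(dout, m$cache$x)
  if (m$use_bias) m$grads$bias <- m$grads$bias + colSums(dout)
  dout %*% m$params$weight
}
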