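# Network assembly: residual blocks (static or ODConv) and the full
# ODConv + coordinate-attention classification network.
#
# Layout (224x224 input): 7x7/2 static stem at the first stage width,
# batch norm, rectifier, 3x3/2 max pool; four stages of residual blocks
# whose 3x3 convolutions are ODConv layers (first block of stages 2-4 has
# stride 2); a coordinate-attention block after each of stages 1-3, whose
# output both feeds the next stage and is tapped for fusion; global
# pooling; FCA fusion of the three tapped features with the final pooled
# feature; affine classifier emitting logits (softmax lives in the
# loss/inference head only).

# ---- residual block ------------------------------------------------------

#' Residual basic block with ODConv or static 3x3 convolutions
#'
#' Two 3x3 convolutions, each followed by batch normalization, a rectifier
#' after the first and after the residual addition. The shortcut is the
#' identity when shapes match, otherwise a 1x1 static convolution with
#' batch normalization. With `dynamic = TRUE` (default) the two 3x3
#' convolutions are [odconv_layer()]s; the stem and shortcut stay static.
#'
#' @param c_in,c_out channel counts.
#' @param stride stride of the first convolution (1 or 2).
#' @param cfg a [net_config()] (or any list with an `odconv` entry)
#'   providing the ODConv settings.
#' @param dynamic use ODConv (TRUE) or static (FALSE) 3x3 convolutions.
#' @return A module.
#' @export
build_odconv_resblock <- function(c_in, c_out, stride = 1L, cfg = net_config(),
                                  dynamic = TRUE) {
  if (!stride %in% c(1L, 2L)) stop("invalid stride: must be 1 or 2")
  od <- cfg$odconv %||% list(n = 4L, gamma = 1 / 16, kernel_attention = "sigmoid")
  mkconv <- function(ci, co, st) {
    if (dynamic) {
      odconv_layer(ci, co, k = 3L, stride = st, pad = 1L, n = od$n,
                   gamma = od$gamma, kernel_attention = od$kernel_attention)
    } else {
      conv_layer(ci, co, k = 3L, stride = st, pad = 1L, bias = FALSE)
    }
  }
  children <- list(
    conv1 = mkconv(c_in, c_out, as.integer(stride)),
    bn1 = batchnorm_layer(c_out),
    relu1 = relu_layer(),
    conv2 = mkconv(c_out, c_out, 1L),
    bn2 = batchnorm_layer(c_out),
    relu_out = relu_layer())
  projected <- (stride != 1L || c_in != c_out)
  if (projected) {
    children$sc_conv <- conv_layer(c_in, c_out, k = 1L, stride = as.integer(stride),
                                   pad = 0L, bias = FALSE)
    children$sc_bn <- batchnorm_layer(c_out)
  }
  new_module("res_block", c_in = c_in, c_out = c_out,
             stride = as.integer(stride), projected = projected,
             dynamic = dynamic, children = children)
}

#' @export
module_forward.res_block <- function(m, x, training = FALSE) {
  ch <- m$children
  t <- module_forward(ch$conv1, x, training)
  t <- module_forward(ch$bn1, t, training)
  t <- module_forward(ch$relu1, t, training)
  t <- module_forward(ch$conv2, t, training)
  t <- module_forward(ch$bn2, t, training)
  sc <- if (m$projected) {
    module_forward(ch$sc_bn, module_forward(ch$sc_conv, x, training), training)
  } else x
  module_forward(ch$relu_out, t + sc, training)
}

#' @export
module_backward.res_block <- function(m, dout) {
  ch <- m$children
  ds <- module_backward(ch$relu_out, dout)
  dt <- module_backward(ch$bn2, ds)
  dt <- module_backward(ch$conv2, dt)
  dt <- module_backward(ch$relu1, dt)
  dt <- module_backward(ch$bn1, dt)
  dx <- module_backward(ch$conv1, dt)
  dsc <- if (m$projected) {
    module_backward(ch$sc_conv, module_backward(ch$sc_bn, ds))
  } else ds
  dx + dsc
}

# ---- global pooling with selectable mode ---------------------------------

globalpool_layer <- function(mode = c("avg", "max")) {
  mode <- match.arg(mode)
  if (mode == "avg") return(gap_layer())
  new_module("gmaxpool_layer")
}

#' @export
module_forward.gmaxpool_layer <- function(m, x, training = FALSE) {
  d <- dim(x)
  xm <- x
  dim(xm) <- c(d[1] * d[2], d[3] * d[4])
  idx <- max.col(xm, ties.method = "first")
  out <- matrix(xm[cbind(seq_len(nrow(xm)), idx)], d[1], d[2])
  if (training) m$cache <- list(dims = d, idx = idx)
  out
}

#' @export
module_backward.gmaxpool_layer <- function(m, dout) {
  d <- m$cache$dims
  dx <- matrix(0, d[1] * d[2], d[3] * d[4])
  dx[cbind(seq_len(nrow(dx)), m$cache$idx)] <- c(dout)
  array(dx, d)
}

# ---- full network --------------------------------------------------------

#' Assemble the ODConv + coordinate-attention classification network
#'
#' @param cfg a [net_config()].
#' @param seed optional integer; when given, parameter initialization is
#'   drawn from a private RNG stream seeded with it, so two builds with the
#'   same seed are bitwise identical.
#' @return A module of class `xodfcanet`.
#' @export
build_xodfcanet <- function(cfg = net_config(), seed = NULL) {
  validate_net_config(cfg)
  with_seed(seed, function() {
    w <- cfg$widths
    children <- list(
      stem_conv = conv_layer(cfg$input_size[1], w[1], k = 7L, stride = 2L,
                             pad = 3L, bias = FALSE),
      stem_bn = batchnorm_layer(w[1]),
      stem_relu = relu_layer(),
      stem_pool = maxpool_layer(3L, 2L, 1L))
    stage_blocks <- vector("list", 4L)
    c_prev <- w[1]
    for (s in 1:4) {
      blocks <- vector("list", cfg$blocks[s])
      for (b in seq_len(cfg$blocks[s])) {
        stride <- if (s > 1L && b == 1L) 2L else 1L
        blocks[[b]] <- build_odconv_resblock(c_prev, w[s], stride, cfg,
                                             dynamic = TRUE)
        c_prev <- w[s]
        children[[sprintf("stage%d_block%d", s, b)]] <- blocks[[b]]
      }
      stage_blocks[[s]] <- blocks
      if (s <= 3L) {
        children[[paste0("ca", s)]] <- coordatt_layer(w[s], r = cfg$ca$r,
                                                      bn_after_reduce = cfg$ca$bn_after_reduce)
      }
    }
    fusion <- cfg$fca$fusion
    D <- if (fusion == "sum") w[4] else cfg$fca$proj_width
    children$fca <- fca_head(w[1:3], D = D, fusion = fusion)
    fc_in <- if (fusion == "sum") w[4] else w[4] + 3L * D
    children$gap_tap1 <- gap_layer()
    children$gap_tap2 <- gap_layer()
    children$gap_tap3 <- gap_layer()
    children$gap_final <- globalpool_layer(cfg$final_pool)
    children$fc <- linear_layer(fc_in, cfg$num_classes, bias = TRUE)
    new_module("xodfcanet", cfg = cfg, stage_blocks = stage_blocks,
               fc_in = fc_in, children = children)
  })
}

#' @export
module_forward.xodfcanet <- function(m, x, training = FALSE) {
  ch <- m$children
  if (dim(x)[2] != m$cfg$input_size[1]) {
    stop(sprintf("dimension error: input has %d channels, network expects %d",
                 dim(x)[2], m$cfg$input_size[1]))
  }
  t <- module_forward(ch$stem_conv, x, training)
  t <- module_forward(ch$stem_bn, t, training)
  t <- module_forward(ch$stem_relu, t, training)
  t <- module_forward(ch$stem_pool, t, training)
  pooled <- vector("list", 3L)
  for (s in 1:4) {
    for (blk in m$stage_blocks[[s]]) t <- module_forward(blk, t, training)
    if (s <= 3L) {
      t <- module_forward(ch[[paste0("ca", s)]], t, training)
      pooled[[s]] <- module_forward(ch[[paste0("gap_tap", s)]], t, training)
    }
  }
  f4 <- module_forward(ch$gap_final, t, training)
  p <- fca_head_forward(ch$fca, pooled, training)
  fused <- if (m$cfg$fca$fusion == "sum") f4 + p else cbind(f4, p)
  module_forward(ch$fc, fused, training)
}

#' @export
module_backward.xodfcanet <- function(m, dout) {
  ch <- m$children
  w4 <- m$cfg$widths[4]
  dfused <- module_backward(ch$fc, dout)
  if (m$cfg$fca$fusion == "sum") {
    df4 <- dfused
    dp <- dfused
  } else {
    df4 <- dfused[, seq_len(w4), drop = FALSE]
    dp <- dfused[, -seq_len(w4), drop = FALSE]
  }
  dpooled <- fca_head_backward(ch$fca, dp)
  dt <- module_backward(ch$gap_final, df4)
  for (s in 4:1) {
    if (s <= 3L) {
      dt <- dt + module_backward(ch[[paste0("gap_tap", s)]], dpooled[[s]])
      dt <- module_backward(ch[[paste0("ca", s)]], dt)
    }
    for (blk in rev(m$stage_blocks[[s]])) dt <- module_backward(blk, dt)
  }
  dt <- module_backward(ch$stem_pool, dt)
  dt <- module_backward(ch$stem_relu, dt)
  dt <- module_backward(ch$stem_bn, dt)
  module_backward(ch$stem_conv, dt)
}

# ---- checkpointing -------------------------------------------------------

collect_state <- function(m, prefix = "") {
  st <- list()
  for (nm in names(m$params)) st[[paste0(prefix, "p.", nm)]] <- m$params[[nm]]
  for (nm in names(m$buffers)) st[[paste0(prefix, "b.", nm)]] <- m$buffers[[nm]]
  for (cn in names(m$children)) {
    st <- c(st, collect_state(m$children[[cn]], paste0(prefix, cn, "/")))
  }
  st
}

apply_state <- function(m, st, prefix = "") {
  for (nm in names(m$params)) {
    key <- paste0(prefix, "p.", nm)
    if (is.null(st[[key]])) stop("checkpoint is missing ", key)
    m$params[[nm]] <- st[[key]]
  }
  for (nm in names(m$buffers)) {
    key <- paste0(prefix, "b.", nm)
    if (!is.null(st[[key]])) m$buffers[[nm]] <- st[[key]]
  }
  for (cn in names(m$children)) {
    apply_state(m$children[[cn]], st, paste0(prefix, cn, "/"))
  }
  invisible(m)
}

#' Save or load a trained network checkpoint
#'
#' The checkpoint stores the [net_config()] plus every parameter and
#' normalization buffer; loading rebuilds the network and restores them.
#'
#' @param model a module built by [build_xodfcanet()].
#' @param path checkpoint file path (RDS).
#' @return `save_model` returns `path` invisibly; `load_model` returns the
#'   restored model.
#' @export
save_model <- function(model, path) {
  saveRDS(list(cfg = model$cfg, state = collect_state(model)), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  ck <- readRDS(path)
  model <- build_xodfcanet(do.call(net_config, unclass(ck$cfg)), seed = 0L)
  apply_state(model, ck$state)
  model
}

#' Class logits for a batch of images
#'
#' Evaluation-mode forward pass (batch-norm running statistics, no caches).
#'
#' @param model a built network module.
#' @param x rank-4 array `N x C x H x W`.
#' @return `N x num_classes` logits matrix.
#' @export
forward_logits <- function(model, x) module_forward(model, x, training = FALSE)
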