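# Plain ResNet-18/50/101 builders (static convolutions, torchvision-style
# layout, resizable classifier head). Their published parameter and MAC
# figures calibrate the package's cost accountant; they can also be run
# forward/backward like any other module.

# Bottleneck residual block: 1x1 reduce, 3x3 (carries the stride), 1x1
# expand (x4), with a projected shortcut when shape changes.
bottleneck_block <- function(c_in, width, stride = 1L, expansion = 4L) {
  c_out <- width * expansion
  children <- list(
    conv1 = conv_layer(c_in, width, k = 1L, stride = 1L, pad = 0L),
    bn1 = batchnorm_layer(width),
    relu1 = relu_layer(),
    conv2 = conv_layer(width, width, k = 3L, stride = as.integer(stride), pad = 1L),
    bn2 = batchnorm_layer(width),
    relu2 = relu_layer(),
    conv3 = conv_layer(width, c_out, k = 1L, stride = 1L, pad = 0L),
    bn3 = batchnorm_layer(c_out),
    relu_out = relu_layer())
  projected <- (stride != 1L || c_in != c_out)
  if (projected) {
    children$sc_conv <- conv_layer(c_in, c_out, k = 1L, stride = as.integer(stride), pad = 0L)
    children$sc_bn <- batchnorm_layer(c_out)
  }
  new_module("bottleneck_block", c_in = c_in, width = width, c_out = c_out,
             stride = as.integer(stride), projected = projected,
             children = children)
}

#' @export
module_forward.bottleneck_block <- function(m, x, training = FALSE) {
  ch <- m$children
  t <- module_forward(ch$relu1, module_forward(ch$bn1, module_forward(ch$conv1, x, training), training), training)
  t <- module_forward(ch$relu2, module_forward(ch$bn2, module_forward(ch$conv2, t, training), training), training)
  t <- module_forward(ch$bn3, module_forward(ch$conv3, t, training), training)
  sc <- if (m$projected) {
    module_forward(ch$sc_bn, module_forward(ch$sc_conv, x, training), training)
  } else x
  module_forward(ch$relu_out, t + sc, training)
}

#' @export
module_backward.bottleneck_block <- function(m, dout) {
  ch <- m$children
  ds <- module_backward(ch$relu_out, dout)
  dt <- module_backward(ch$conv3, module_backward(ch$bn3, ds))
  dt <- module_backward(ch$relu2, dt)
  dt <- module_backward(ch$conv2, module_backward(ch$bn2, dt))
  dt <- module_backward(ch$relu1, dt)
  dx <- module_backward(ch$conv1, module_backward(ch$bn1, dt))
  dsc <- if (m$projected) {
    module_backward(ch$sc_conv, module_backward(ch$sc_bn, ds))
  } else ds
  dx + dsc
}

# Shared ResNet skeleton.
build_resnet <- function(layers, block = c("basic", "bottleneck"),
                         num_classes = 3L, in_channels = 3L, seed = NULL) {
  block <- match.arg(block)
  if (num_classes < 2L) stop("num_classes must be >= 2")
  with_seed(seed, function() {
    widths <- c(64L, 128L, 256L, 512L)
    expansion <- if (block == "bottleneck") 4L else 1L
    children <- list(
      stem_conv = conv_layer(in_channels, 64L, k = 7L, stride = 2L, pad = 3L),
      stem_bn = batchnorm_layer(64L),
      stem_relu = relu_layer(),
      stem_pool = maxpool_layer(3L, 2L, 1L))
    stage_blocks <- vector("list", 4L)
    c_prev <- 64L
    for (s in 1:4) {
      blocks <- vector("list", layers[s])
      for (b in seq_len(layers[s])) {
        stride <- if (s > 1L && b == 1L) 2L else 1L
        blocks[[b]] <- if (block == "basic") {
          build_odconv_resblock(c_prev, widths[s], stride, dynamic = FALSE)
        } else {
          bottleneck_block(c_prev, widths[s], stride, expansion)
        }
        c_prev <- widths[s] * expansion
        children[[sprintf("stage%d_block%d", s, b)]] <- blocks[[b]]
      }
      stage_blocks[[s]] <- blocks
    }
    children$gap <- gap_layer()
    children$fc <- linear_layer(512L * expansion, as.integer(num_classes), bias = TRUE)
    new_module("resnet", layers = layers, block = block,
               num_classes = as.integer(num_classes),
               stage_blocks = stage_blocks, children = children)
  })
}

#' @export
module_forward.resnet <- function(m, x, training = FALSE) {
  ch <- m$children
  t <- module_forward(ch$stem_conv, x, training)
  t <- module_forward(ch$stem_bn, t, training)
  t <- module_forward(ch$stem_relu, t, training)
  t <- module_forward(ch$stem_pool, t, training)
  for (s in 1:4) for (blk in m$stage_blocks[[s]]) t <- module_forward(blk, t, training)
  module_forward(ch$fc, module_forward(ch$gap, t, training), training)
}

#' @export
module_backward.resnet <- function(m, dout) {
  ch <- m$children
  dt <- module_backward(ch$gap, module_backward(ch$fc, dout))
  for (s in 4:1) for (blk in rev(m$stage_blocks[[s]])) dt <- module_backward(blk, dt)
  dt <- module_backward(ch$stem_pool, dt)
  dt <- module_backward(ch$stem_relu, dt)
  module_backward(ch$stem_conv, module_backward(ch$stem_bn, dt))
}

#' Plain ResNet baselines with a resizable classifier head
#'
#' Standard torchvision-convention architectures (static convolutions
#' only), used to pin the accountant's conventions against published
#' parameter/MAC figures.
#'
#' @param num_classes number of classes (>= 2).
#' @param seed optional seed for deterministic initialization.
#' @return A module.
#' @export
build_resnet18_baseline <- function(num_classes = 3L, seed = NULL) {
  build_resnet(c(2L, 2L, 2L, 2L), "basic", num_classes, seed = seed)
}

#' @rdname build_resnet18_baseline
#' @export
build_resnet50_baseline <- function(num_classes = 3L, seed = NULL) {
  build_resnet(c(3L, 4L, 6L, 3L), "bottleneck", num_classes, seed = seed)
}

#' @rdname build_resnet18_baseline
#' @export
build_resnet101_baseline <- function(num_classes = 3L, seed = NULL) {
  build_resnet(c(3L, 4L, 23L, 3L), "bottleneck", num_classes, seed = seed)
}
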