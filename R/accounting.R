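# Exact cost accounting: trainable-parameter counts and multiply-accumulate
# (MAC) counts for one forward pass of a single sample.
#
# Conventions (calibrated against the published ResNet figures, which
# follow the 1-FLOP-per-MAC convention):
#   * convolution: Ho * Wo * c_out * c_in * k^2 MACs (bias adds excluded);
#   * affine map:  in * out MACs;
#   * ODConv adds its attention-head affine MACs once per sample;
#   * coordinate attention adds its 1x1 reduce/expand transforms over the
#     (H + W) pooled positions;
#   * pooling, normalization and elementwise gating are excluded.

#' Count trainable parameters of a model
#'
#' Number of trainable scalars over every parameter array in the module
#' tree (batch-norm running statistics are buffers, not parameters).
#'
#' @param model a module.
#' @return Numeric scalar count.
#' @export
count_parameters <- function(model) {
  sum(vapply(module_param_list(model), length, numeric(1)))
}

# Per-module cost walker: returns list(rows = data.frame, out_shape).
# in_shape is c(C, H, W) for feature maps or a single width for vectors.
module_cost <- function(m, in_shape, name) UseMethod("module_cost")

cost_row <- function(name, type, out_shape, params, macs) {
  data.frame(layer = name, type = type,
             output = paste(out_shape, collapse = "x"),
             params = params, macs = macs, stringsAsFactors = FALSE)
}

n_params_local <- function(m) sum(vapply(m$params, length, numeric(1)))

#' @export
module_cost.conv_layer <- function(m, in_shape, name) {
  Ho <- conv_out_size(in_shape[2], m$k, m$stride, m$pad)
  Wo <- conv_out_size(in_shape[3], m$k, m$stride, m$pad)
  macs <- Ho * Wo * m$c_out * m$c_in * m$k^2
  out <- c(m$c_out, Ho, Wo)
  list(rows = cost_row(name, "conv", out, n_params_local(m), macs), out_shape = out)
}

#' @export
module_cost.odconv_layer <- function(m, in_shape, name) {
  Ho <- conv_out_size(in_shape[2], m$k, m$stride, m$pad)
  Wo <- conv_out_size(in_shape[3], m$k, m$stride, m$pad)
  conv_macs <- Ho * Wo * m$c_out * m$c_in * m$k^2
  attn_macs <- m$c_in * m$s + m$s * (m$k^2 + m$c_in + m$c_out + m$n)
  out <- c(m$c_out, Ho, Wo)
  list(rows = cost_row(name, "odconv", out, n_params_local(m), conv_macs + attn_macs),
       out_shape = out)
}

#' @export
module_cost.batchnorm_layer <- function(m, in_shape, name) {
  list(rows = cost_row(name, "batchnorm", in_shape, n_params_local(m), 0),
       out_shape = in_shape)
}

#' @export
module_cost.batchnorm1d_layer <- function(m, in_shape, name) {
  list(rows = cost_row(name, "batchnorm", in_shape, n_params_local(m), 0),
       out_shape = in_shape)
}

#' @export
module_cost.relu_layer <- function(m, in_shape, name) {
  list(rows = cost_row(name, "relu", in_shape, 0, 0), out_shape = in_shape)
}

#' @export
module_cost.maxpool_layer <- function(m, in_shape, name) {
  Ho <- conv_out_size(in_shape[2], m$k, m$stride, m$pad)
  Wo <- conv_out_size(in_shape[3], m$k, m$stride, m$pad)
  out <- c(in_shape[1], Ho, Wo)
  list(rows = cost_row(name, "maxpool", out, 0, 0), out_shape = out)
}

#' @export
module_cost.gap_layer <- function(m, in_shape, name) {
  out <- in_shape[1]
  list(rows = cost_row(name, "globalpool", out, 0, 0), out_shape = out)
}

#' @export
module_cost.gmaxpool_layer <- function(m, in_shape, name) {
  out <- in_shape[1]
  list(rows = cost_row(name, "globalpool", out, 0, 0), out_shape = out)
}

#' @export
module_cost.linear_layer <- function(m, in_shape, name) {
  list(rows = cost_row(name, "linear", m$d_out, n_params_local(m),
                       m$d_in * m$d_out),
       out_shape = m$d_out)
}

#' @export
module_cost.coordatt_layer <- function(m, in_shape, name) {
  H <- in_shape[2]; W <- in_shape[3]
  macs <- (H + W) * m$c_red * m$C +          # shared reduce transform
    H * m$C * m$c_red + W * m$C * m$c_red    # per-direction expands
  params <- n_params_local(m) +
    if (m$bn_after_reduce) n_params_local(m$children$bn) else 0
  list(rows = cost_row(name, "coordatt", in_shape, params, macs),
       out_shape = in_shape)
}

# Residual blocks: recurse over children in execution order; the block's
# output shape is the main-branch output shape.
block_cost <- function(m, in_shape, name, order) {
  rows <- NULL
  shape <- in_shape
  for (nm in order) {
    r <- module_cost(m$children[[nm]], shape, paste0(name, ".", nm))
    rows <- rbind(rows, r$rows)
    shape <- r$out_shape
  }
  if (m$projected) {
    r1 <- module_cost(m$children$sc_conv, in_shape, paste0(name, ".sc_conv"))
    r2 <- module_cost(m$children$sc_bn, r1$out_shape, paste0(name, ".sc_bn"))
    rows <- rbind(rows, r1$rows, r2$rows)
  }
  list(rows = rows, out_shape = shape)
}

#' @export
module_cost.res_block <- function(m, in_shape, name) {
  block_cost(m, in_shape, name,
             c("conv1", "bn1", "relu1", "conv2", "bn2", "relu_out"))
}

#' @export
module_cost.bottleneck_block <- function(m, in_shape, name) {
  block_cost(m, in_shape, name,
             c("conv1", "bn1", "relu1", "conv2", "bn2", "relu2",
               "conv3", "bn3", "relu_out"))
}

#' @export
module_cost.fca_head <- function(m, in_shape, name) {
  rows <- NULL
  for (i in seq_len(m$n_stage)) {
    r <- module_cost(m$children[[i]], in_shape = NULL,
                     paste0(name, ".proj", i))
    rows <- rbind(rows, r$rows)
  }
  out <- if (m$fusion == "sum") m$D else m$n_stage * m$D
  list(rows = rows, out_shape = out)
}

#' @export
module_cost.xodfcanet <- function(m, in_shape, name) {
  ch <- m$children
  rows <- NULL
  shape <- in_shape
  for (nm in c("stem_conv", "stem_bn", "stem_relu", "stem_pool")) {
    r <- module_cost(ch[[nm]], shape, nm)
    rows <- rbind(rows, r$rows)
    shape <- r$out_shape
  }
  for (s in 1:4) {
    for (b in seq_along(m$stage_blocks[[s]])) {
      r <- module_cost(m$stage_blocks[[s]][[b]], shape,
                       sprintf("stage%d.block%d", s, b))
      rows <- rbind(rows, r$rows)
      shape <- r$out_shape
    }
    if (s <= 3L) {
      r <- module_cost(ch[[paste0("ca", s)]], shape, paste0("ca", s))
      rows <- rbind(rows, r$rows)
      shape <- r$out_shape
    }
  }
  r <- module_cost(ch$gap_final, shape, "global_pool")
  rows <- rbind(rows, r$rows)
  r <- module_cost(ch$fca, NULL, "fca")
  rows <- rbind(rows, r$rows)
  r <- module_cost(ch$fc, m$fc_in, "fc")
  rows <- rbind(rows, r$rows)
  list(rows = rows, out_shape = m$cfg$num_classes)
}

#' @export
module_cost.resnet <- function(m, in_shape, name) {
  ch <- m$children
  rows <- NULL
  shape <- in_shape
  for (nm in c("stem_conv", "stem_bn", "stem_relu", "stem_pool")) {
    r <- module_cost(ch[[nm]], shape, nm)
    rows <- rbind(rows, r$rows)
    shape <- r$out_shape
  }
  for (s in 1:4) {
    for (b in seq_along(m$stage_blocks[[s]])) {
      r <- module_cost(m$stage_blocks[[s]][[b]], shape,
                       sprintf("stage%d.block%d", s, b))
      rows <- rbind(rows, r$rows)
      shape <- r$out_shape
    }
  }
  r <- module_cost(ch$gap, shape, "global_pool")
  rows <- rbind(rows, r$rows)
  r <- module_cost(ch$fc, shape[1], "fc")
  rows <- rbind(rows, r$rows)
  list(rows = rows, out_shape = m$num_classes)
}

#' Parameter and MAC summary of a model
#'
#' Walks the model exactly as its forward pass does and tabulates every
#' layer's trainable parameters and per-sample MACs.
#'
#' @param model a built network module.
#' @param input_size `c(channels, height, width)`; defaults to the model's
#'   configured input size (224x224 RGB for baselines).
#' @return An object of class `model_summary`: list with `layers` (per-layer
#'   data frame), `total_params` and `total_macs`.
#' @export
model_summary <- function(model, input_size = NULL) {
  if (is.null(input_size)) {
    input_size <- if (!is.null(model$cfg)) model$cfg$input_size else c(3L, 224L, 224L)
  }
  r <- module_cost(model, as.numeric(input_size), "net")
  structure(list(layers = r$rows,
                 total_params = sum(r$rows$params),
                 total_macs = sum(r$rows$macs),
                 input_size = input_size),
            class = "model_summary")
}

#' Count multiply-accumulates of one forward pass
#'
#' @inheritParams model_summary
#' @return Numeric MAC count for a single sample.
#' @export
count_macs <- function(model, input_size = NULL) {
  model_summary(model, input_size)$total_macs
}

#' @export
print.model_summary <- function(x, ...) {
  df <- x$layers
  df$params <- format(df$params, big.mark = ",", scientific = FALSE)
  df$macs <- format(df$macs, big.mark = ",", scientific = FALSE)
  cat(sprintf("Input size: %s\n", paste(x$input_size, collapse = "x")))
  print(df, row.names = FALSE, right = FALSE)
  cat(sprintf("\nTotal trainable parameters: %s (%.2fM)\n",
              format(x$total_params, big.mark = ","), x$total_params / 1e6))
  cat(sprintf("Total MACs per sample:      %s (%.2fM)\n",
              format(x$total_macs, big.mark = ","), x$total_macs / 1e6))
  invisible(x)
}

#' @export
format.model_summary <- function(x, ...) {
  sprintf("model_summary: %.4fM params, %.2fM MACs", x$total_params / 1e6,
          x$total_macs / 1e6)
}

#' JSON representation of a model summary
#'
#' @param x a [model_summary()].
#' @return JSON string with totals and the per-layer table.
#' @export
model_summary_json <- function(x) {
  jsonlite::toJSON(list(input_size = x$input_size,
                        total_params = x$total_params,
                        total_macs = x$total_macs,
                        layers = x$layers),
                   auto_unbox = TRUE, digits = NA)
}
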