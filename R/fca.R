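# Feature coordinate attention (FCA): fuses coordinate-attention outputs
# taken at several network depths. Each tapped feature map is globally
# average-pooled to a vector, linearly projected to a common width, and
# the projected vectors are combined -- summed by default, optionally
# concatenated.

#' FCA fusion parameters
#'
#' @param projections list with one entry per tapped stage: a `D x C_stage`
#'   projection matrix, or `NULL` for the identity (stage width must then
#'   already equal the fusion width).
#' @param fusion `"sum"` or `"concat"`.
#' @return An object of class `fca_params`.
#' @export
fca_params <- function(projections, fusion = c("sum", "concat")) {
  fusion <- match.arg(fusion)
  if (!length(projections)) stop("projections must be a non-empty list")
  structure(list(projections = projections, fusion = fusion),
            class = "fca_params")
}

#' FCA forward pass (functional form)
#'
#' Pools every tapped stage to a vector with [channel_global_pool()],
#' projects each to the common width, and fuses.
#'
#' @param stage_features non-empty list of rank-4 arrays (one per tap).
#' @param p an [fca_params()] with one projection per stage.
#' @return `N x D` matrix (`sum` mode) or `N x (n_stage * D)` (`concat`).
#' @export
fca_forward <- function(stage_features, p) {
  if (!length(stage_features)) stop("stage_features must be a non-empty list")
  if (length(stage_features) != length(p$projections)) {
    stop(sprintf("configuration error: %d stages but %d projections",
                 length(stage_features), length(p$projections)))
  }
  proj <- vector("list", length(stage_features))
  for (i in seq_along(stage_features)) {
    g <- channel_global_pool(stage_features[[i]])
    pm <- p$projections[[i]]
    proj[[i]] <- if (is.null(pm)) g else {
      if (ncol(pm) != ncol(g)) {
        stop(sprintf("configuration error: projection %d maps %d channels but stage has %d",
                     i, ncol(pm), ncol(g)))
      }
      tcrossprod(g, pm)
    }
  }
  widths <- vapply(proj, ncol, integer(1))
  if (p$fusion == "sum") {
    if (length(unique(widths)) != 1L) {
      stop(sprintf("configuration error: projected widths differ (%s); sum fusion needs one width",
                   paste(widths, collapse = ", ")))
    }
    Reduce(`+`, proj)
  } else {
    do.call(cbind, proj)
  }
}

# ---- trainable fusion head ----------------------------------------------
#
# The network module owns the linear projection layers; this module groups
# them and implements fused forward/backward over (already pooled) vectors.

fca_head <- function(stage_widths, D, fusion = c("sum", "concat"), bias = TRUE) {
  fusion <- match.arg(fusion)
  projs <- lapply(stage_widths, function(w) linear_layer(w, D, bias = bias))
  names(projs) <- paste0("proj", seq_along(projs))
  new_module("fca_head", D = D, fusion = fusion,
             n_stage = length(stage_widths), children = projs)
}

# pooled: list of (N x C_stage) matrices, one per tap.
fca_head_forward <- function(m, pooled, training = FALSE) {
  outs <- vector("list", m$n_stage)
  for (i in seq_len(m$n_stage)) {
    outs[[i]] <- module_forward(m$children[[i]], pooled[[i]], training)
  }
  if (m$fusion == "sum") Reduce(`+`, outs) else do.call(cbind, outs)
}

# Returns list of gradients, one per pooled input.
fca_head_backward <- function(m, dout) {
  dpooled <- vector("list", m$n_stage)
  if (m$fusion == "sum") {
    for (i in seq_len(m$n_stage)) {
      dpooled[[i]] <- module_backward(m$children[[i]], dout)
    }
  } else {
    off <- 0L
    for (i in seq_len(m$n_stage)) {
      D <- m$children[[i]]$d_out
      dpooled[[i]] <- module_backward(m$children[[i]],
                                      dout[, off + seq_len(D), drop = FALSE])
      off <- off + D
    }
  }
  dpooled
}
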