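# Low-level array kernels shared by every layer: zero-padding, im2col /
# col2im lowering of 2-d convolution onto BLAS matrix products, pooling,
# and the broadcast helpers used for channel/spatial gating.
#
# All feature tensors are dense double arrays with dim = c(N, C, H, W).
# R arrays are column-major, so the sample index varies fastest; the
# broadcast helpers below exploit that layout for copy-free recycling.

#' Output size of a strided convolution or pooling window
#'
#' Standard convolution arithmetic: floor((size + 2*pad - k) / stride) + 1.
#'
#' @param size input spatial extent (height or width).
#' @param k window size.
#' @param stride step between windows.
#' @param pad zero-padding added on each side.
#' @return Integer output extent.
#' @export
conv_out_size <- function(size, k, stride = 1L, pad = 0L) {
  as.integer(floor((size + 2L * pad - k) / stride) + 1L)
}

# Zero-pad the two spatial dims of an (N,C,H,W) array.
pad4d <- function(x, pad, value = 0) {
  if (pad == 0L) return(x)
  d <- dim(x)
  xp <- array(value, c(d[1], d[2], d[3] + 2L * pad, d[4] + 2L * pad))
  xp[, , pad + seq_len(d[3]), pad + seq_len(d[4])] <- x
  xp
}

# Lower convolution patches to a matrix.
#
# sample_blocks = FALSE: rows ordered (n, ho, wo) with n fastest; one GEMM
#   against a shared kernel serves the whole batch (static convolution).
# sample_blocks = TRUE: rows ordered (ho, wo, n), so rows of sample i are
#   the contiguous block (i-1)*Ho*Wo + 1:(Ho*Wo); needed when every sample
#   has its own kernel (dynamic convolution).
#
# Returns list(mat, N, C, H, W, Ho, Wo, k, stride, pad, sample_blocks).
im2col <- function(x, k, stride = 1L, pad = 0L, sample_blocks = FALSE) {
  d <- dim(x)
  N <- d[1]; C <- d[2]; H <- d[3]; W <- d[4]
  Ho <- conv_out_size(H, k, stride, pad)
  Wo <- conv_out_size(W, k, stride, pad)
  if (Ho < 1L || Wo < 1L) {
    stop(sprintf(
      "configuration error: non-positive output spatial size (%d x %d) for input %d x %d, k = %d, stride = %d, pad = %d",
      Ho, Wo, H, W, k, stride, pad))
  }
  xp <- pad4d(x, pad)
  cols <- array(0, c(N, C, k, k, Ho, Wo))
  for (u in seq_len(k)) {
    rows <- (seq_len(Ho) - 1L) * stride + u
    for (v in seq_len(k)) {
      ccols <- (seq_len(Wo) - 1L) * stride + v
      cols[, , u, v, , ] <- xp[, , rows, ccols]
    }
  }
  perm <- if (sample_blocks) c(5L, 6L, 1L, 2L, 3L, 4L) else c(1L, 5L, 6L, 2L, 3L, 4L)
  mat <- matrix(aperm(cols, perm), N * Ho * Wo, C * k * k)
  list(mat = mat, N = N, C = C, H = H, W = W, Ho = Ho, Wo = Wo,
       k = k, stride = stride, pad = pad, sample_blocks = sample_blocks)
}

# Inverse of im2col: scatter-add patch gradients back onto the input grid.
# `dmat` has the row ordering recorded in `info`.
col2im <- function(dmat, info) {
  N <- info$N; C <- info$C; H <- info$H; W <- info$W
  Ho <- info$Ho; Wo <- info$Wo; k <- info$k
  stride <- info$stride; pad <- info$pad
  dims <- if (info$sample_blocks) c(Ho, Wo, N, C, k, k) else c(N, Ho, Wo, C, k, k)
  dcols <- array(dmat, dims)
  perm <- if (info$sample_blocks) c(3L, 4L, 5L, 6L, 1L, 2L) else c(1L, 4L, 5L, 6L, 2L, 3L)
  dcols <- aperm(dcols, perm)  # (N, C, k, k, Ho, Wo)
  dxp <- array(0, c(N, C, H + 2L * pad, W + 2L * pad))
  for (u in seq_len(k)) {
    rows <- (seq_len(Ho) - 1L) * stride + u
    for (v in seq_len(k)) {
      ccols <- (seq_len(Wo) - 1L) * stride + v
      piece <- dcols[, , u, v, , , drop = FALSE]
      dim(piece) <- c(N, C, Ho, Wo)
      dxp[, , rows, ccols] <- dxp[, , rows, ccols, drop = FALSE] + piece
    }
  }
  if (pad > 0L) dxp[, , pad + seq_len(H), pad + seq_len(W), drop = FALSE] else dxp
}

# Reshape a kernel array (c_out, c_in, k, k) to the (C*k*k) x c_out matrix
# matching im2col's column ordering.
kernel_to_mat <- function(w) {
  d <- dim(w)
  matrix(aperm(w, c(2L, 3L, 4L, 1L)), d[2] * d[3] * d[4], d[1])
}

# Inverse of kernel_to_mat.
mat_to_kernel <- function(m, c_out, c_in, k) {
  aperm(array(m, c(c_in, k, k, c_out)), c(4L, 1L, 2L, 3L))
}

# ---- broadcast helpers ------------------------------------------------

# x (N,C,H,W) * m (N,C), broadcast over H,W. Exact recycling: the flat
# layout of x repeats the (n,c) plane once per spatial position.
bmul_nc <- function(x, m) x * c(m)

# x (N,C,H,W) * v (length C), broadcast over N,H,W.
bmul_c <- function(x, v) x * rep(v, each = dim(x)[1])

# x (N,C,H,W) * a (N,C,H), broadcast over W.
bmul_nch <- function(x, a) x * c(a)

# x (N,C,H,W) * a (N,C,W), broadcast over H.
bmul_ncw <- function(x, a) {
  H <- dim(x)[3]; W <- dim(x)[4]
  x * c(a[, , rep(seq_len(W), each = H), drop = FALSE])
}

# Expand a (N,C,W) over H (used by pooling backward).
expand_ncw <- function(a, H) {
  W <- dim(a)[3]
  arr <- a[, , rep(seq_len(W), each = H), drop = FALSE]
  dim(arr) <- c(dim(a)[1], dim(a)[2], H, W)
  arr
}

# Sum x (N,C,H,W) over the spatial dims -> (N,C) matrix.
rsum_spatial <- function(x) {
  d <- dim(x)
  dim(x) <- c(d[1] * d[2], d[3] * d[4])
  matrix(rowSums(x), d[1], d[2])
}

# Mean over W -> (N,C,H); mean over H -> (N,C,W).
mean_over_w <- function(x) {
  d <- dim(x)
  dim(x) <- c(d[1] * d[2] * d[3], d[4])
  array(rowMeans(x), d[1:3])
}
mean_over_h <- function(x) {
  d <- dim(x)
  x <- aperm(x, c(1L, 2L, 4L, 3L))
  dim(x) <- c(d[1] * d[2] * d[4], d[3])
  array(rowMeans(x), c(d[1], d[2], d[4]))
}
sum_over_w <- function(x) {
  d <- dim(x)
  dim(x) <- c(d[1] * d[2] * d[3], d[4])
  array(rowSums(x), d[1:3])
}
sum_over_h <- function(x) {
  d <- dim(x)
  x <- aperm(x, c(1L, 2L, 4L, 3L))
  dim(x) <- c(d[1] * d[2] * d[4], d[3])
  array(rowSums(x), c(d[1], d[2], d[4]))
}

# ---- numerics ---------------------------------------------------------

sigmoid <- function(x) 1 / (1 + exp(-x))

relu <- function(x) {
  x[x < 0] <- 0
  x
}

# Evaluate f() under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards. Used everywhere determinism is promised.
with_seed <- function(seed, f) {
  if (is.null(seed)) return(f())
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% 2147483647))
  f()
}

# Kaiming/He normal init for a convolution kernel or affine weight.
he_init <- function(dims, fan_in) {
  array(stats::rnorm(prod(dims), sd = sqrt(2 / fan_in)), dims)
}
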