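# Independent oracles and small utilities shared by the tests. Everything
# here is written as straight-line / nested-loop code, deliberately not
# reusing the package's vectorized implementations.

# Brute-force sliding-window convolution (no bias).
naive_conv <- function(x, w, stride = 1L, pad = 0L) {
  d <- dim(x); N <- d[1]; C <- d[2]; H <- d[3]; W <- d[4]
  kd <- dim(w); co <- kd[1]; k <- kd[3]
  Ho <- floor((H + 2 * pad - k) / stride) + 1
  Wo <- floor((W + 2 * pad - k) / stride) + 1
  xp <- array(0, c(N, C, H + 2 * pad, W + 2 * pad))
  xp[, , pad + seq_len(H), pad + seq_len(W)] <- x
  out <- array(0, c(N, co, Ho, Wo))
  for (n in seq_len(N)) for (o in seq_len(co)) for (i in seq_len(Ho)) for (j in seq_len(Wo)) {
    acc <- 0
    for (c in seq_len(C)) for (u in seq_len(k)) for (v in seq_len(k)) {
      acc <- acc + xp[n, c, (i - 1) * stride + u, (j - 1) * stride + v] * w[o, c, u, v]
    }
    out[n, o, i, j] <- acc
  }
  out
}

# Straight-line recomputation of the ODConv attention pipeline for one
# sample, using explicit loops for the pooling and plain matrix-vector
# arithmetic for the affine maps.
naive_attention <- function(x1, head) {
  C <- dim(x1)[1]; H <- dim(x1)[2]; W <- dim(x1)[3]
  z <- numeric(C)
  for (c in seq_len(C)) {
    s <- 0
    for (i in seq_len(H)) for (j in seq_len(W)) s <- s + x1[c, i, j]
    z[c] <- s / (H * W)
  }
  h <- pmax(as.numeric(head$w_sq %*% z + head$b_sq), 0)
  sig <- function(t) 1 / (1 + exp(-t))
  list(alpha_s = sig(as.numeric(head$w_s %*% h + head$b_s)),
       alpha_c = sig(as.numeric(head$w_c %*% h + head$b_c)),
       alpha_f = sig(as.numeric(head$w_f %*% h + head$b_f)),
       alpha_w = sig(as.numeric(head$w_w %*% h + head$b_w)))
}

# Quintuple-nested-loop oracle for the effective-kernel aggregation.
naive_effective_kernel <- function(alpha_s, alpha_c, alpha_f, alpha_w, kernels) {
  d <- dim(kernels) # n, c_out, c_in, k, k
  out <- array(0, d[2:5])
  for (t in seq_len(d[1])) for (o in seq_len(d[2])) for (c in seq_len(d[3]))
    for (u in seq_len(d[4])) for (v in seq_len(d[5])) {
      out[o, c, u, v] <- out[o, c, u, v] +
        alpha_w[t] * kernels[t, o, c, u, v] * alpha_s[u, v] * alpha_c[c] * alpha_f[o]
    }
  out
}

# Independent closed-form parameter/MAC calculator for the assembled
# network (mirrors the documented architecture, not the accountant code).
closed_form_cost <- function(cfg) {
  w <- cfg$widths
  n <- cfg$odconv$n; gamma <- cfg$odconv$gamma; r <- cfg$ca$r
  input <- cfg$input_size[2]
  sq <- function(ci) max(1, floor(ci * gamma))
  od_p <- function(ci, co) {
    s <- sq(ci)
    n * co * ci * 9 + s * (ci + 1) + (9 + ci + co + n) * (s + 1)
  }
  od_m <- function(ci, co, hw) {
    s <- sq(ci)
    hw^2 * co * ci * 9 + ci * s + s * (9 + ci + co + n)
  }
  P <- w[1] * cfg$input_size[1] * 49 + 2 * w[1]
  M <- (input / 2)^2 * w[1] * cfg$input_size[1] * 49
  hw <- input / 4
  c_prev <- w[1]
  for (s in 1:4) {
    for (b in seq_len(cfg$blocks[s])) {
      stride <- if (s > 1 && b == 1) 2 else 1
      if (stride == 2) hw <- hw / 2
      P <- P + od_p(c_prev, w[s]) + od_p(w[s], w[s]) + 4 * w[s]
      M <- M + od_m(c_prev, w[s], hw) + od_m(w[s], w[s], hw)
      if (stride != 1 || c_prev != w[s]) {
        P <- P + c_prev * w[s] + 2 * w[s]
        M <- M + hw^2 * c_prev * w[s]
      }
      c_prev <- w[s]
    }
    if (s <= 3) {
      cr <- floor(w[s] / r)
      P <- P + cr * w[s] + cr + 2 * (w[s] * cr + w[s]) +
        (if (isTRUE(cfg$ca$bn_after_reduce)) 2 * cr else 0)
      M <- M + 2 * (2 * hw) * w[s] * cr
    }
  }
  D <- w[4]
  P <- P + sum(w[1:3] * D + D) + D * cfg$num_classes + cfg$num_classes
  M <- M + sum(w[1:3] * D) + D * cfg$num_classes
  list(params = P, macs = M)
}

# ---- numerical gradient checking ----------------------------------------

collect_grads <- function(mm, prefix = "") {
  out <- list()
  for (nm in names(mm$params)) out[[paste0(prefix, nm)]] <- mm$grads[[nm]]
  for (cn in names(mm$children)) {
    out <- c(out, collect_grads(mm$children[[cn]], paste0(prefix, cn, ".")))
  }
  out
}

get_param_by_path <- function(mm, path) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  while (length(parts) > 1) { mm <- mm$children[[parts[1]]]; parts <- parts[-1] }
  mm$params[[parts[1]]]
}

set_param_by_path <- function(mm, path, val) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  while (length(parts) > 1) { mm <- mm$children[[parts[1]]]; parts <- parts[-1] }
  p <- mm$params[[parts[1]]]; p[] <- val; mm$params[[parts[1]]] <- p
}

reset_bn_buffers <- function(mm) {
  walk_modules(mm, function(z) {
    if (!is.null(z$buffers)) {
      z$buffers$running_mean[] <- 0
      z$buffers$running_var[] <- 1
    }
  })
}

# Worst relative error between analytic and central-difference gradients,
# probing `npick` random coordinates of the input and of every parameter.
grad_check_worst <- function(m, x, eps = 1e-5, npick = 4) {
  out0 <- module_forward(m, x, TRUE)
  wts <- out0; wts[] <- stats::rnorm(length(out0))
  loss_fn <- function() {
    reset_bn_buffers(m)
    sum(module_forward(m, x, TRUE) * wts)
  }
  reset_bn_buffers(m)
  zero_grads(m)
  invisible(module_forward(m, x, TRUE))
  dx <- module_backward(m, wts)
  gr <- collect_grads(m)
  worst <- 0
  probe <- function(g, getv, setv) {
    th <- getv()
    idx <- sample(length(th), min(npick, length(th)))
    for (i in idx) {
      th2 <- th; th2[i] <- th[i] + eps; setv(th2); lp <- loss_fn()
      th2[i] <- th[i] - eps; setv(th2); lm <- loss_fn()
      setv(th)
      num <- (lp - lm) / (2 * eps)
      worst <<- max(worst, abs(num - g[i]) / max(1, abs(num), abs(g[i])))
    }
  }
  probe(dx, function() x, function(v) { x2 <- x; x2[] <- v; x <<- x2 })
  for (nm in names(gr)) {
    probe(gr[[nm]], function() get_param_by_path(m, nm),
          function(v) set_param_by_path(m, nm, v))
  }
  worst
}

# Small in-memory synthetic dataset for training tests (generated once per
# test run, cached in the session).
tiny_cxr_dataset <- function(per_class, size, seed = 1L, img_size = 224L) {
  dir <- file.path(tempdir(),
                   sprintf("odfcanet-tiny-%d-%d-%d-%d", per_class, size, seed, img_size))
  if (!dir.exists(dir)) {
    generate_cxr_dataset(synthetic_spec(per_class = per_class, size = img_size,
                                        seed = seed), dir)
  }
  load_cxr_dataset(dir, size = size, standardize = TRUE)
}
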