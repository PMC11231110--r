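# Deterministic synthetic chest-radiograph generator. Three classes that
# mimic the gross appearance of frontal CXRs at the level a desk-scale
# classifier needs: two dark elliptical lung fields on a brighter
# mediastinum/chest-wall background, plus class-specific opacities.
#   normal    - lung fields left dark (plus acquisition noise);
#   pneumonia - one focal bright consolidation blob inside a lung field;
#   covid     - several diffuse low-contrast opacities in the peripheral
#               lung zones of both lungs.
# The recipes are deliberately highly separable so training-based checks
# are fast and robust; they emulate folder-per-class PNG corpora, not the
# statistics of real radiographs.

#' Classes emitted by the synthetic generator
#' @return Character vector of class labels in canonical order.
#' @export
cxr_classes <- function() c("covid", "pneumonia", "normal")

#' Specification of a synthetic chest-radiograph dataset
#'
#' @param per_class images per class (>= 1).
#' @param size square image side in pixels.
#' @param noise_sd Gaussian pixel-noise standard deviation (0-255 scale).
#' @param seed integer master seed; every image derives its own stream.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(per_class = 50L, size = 224L, noise_sd = 8,
                           seed = 1L) {
  if (per_class < 1L) stop("per_class must be >= 1")
  if (size < 32L) stop("size must be >= 32 pixels")
  structure(list(per_class = as.integer(per_class), size = as.integer(size),
                 noise_sd = noise_sd, seed = as.integer(seed),
                 classes = cxr_classes()),
            class = "synthetic_spec")
}

# Ellipse interior indicator on a size x size grid (rows = y, cols = x),
# all coordinates as fractions of the side.
ellipse_mask <- function(size, cx, cy, rx, ry) {
  xs <- (seq_len(size) - 0.5) / size
  ys <- (seq_len(size) - 0.5) / size
  outer(ys, xs, function(y, x) ((x - cx) / rx)^2 + ((y - cy) / ry)^2 <= 1)
}

# Gaussian bump (peak 1) centered at (cx, cy) with sd `s`, fractions of side.
gaussian_bump <- function(size, cx, cy, s) {
  xs <- (seq_len(size) - 0.5) / size
  ys <- (seq_len(size) - 0.5) / size
  outer(ys, xs, function(y, x) exp(-((x - cx)^2 + (y - cy)^2) / (2 * s^2)))
}

# Geometry shared by all classes.
lung_geometry <- function() {
  list(left = list(cx = 0.32, cy = 0.55, rx = 0.17, ry = 0.30),
       right = list(cx = 0.68, cy = 0.55, rx = 0.17, ry = 0.30))
}

#' Lung-field mask used by the synthetic recipes
#'
#' @param size square image side in pixels.
#' @return Logical `size x size` matrix, `TRUE` inside either lung ellipse.
#' @export
lung_field_mask <- function(size) {
  g <- lung_geometry()
  ellipse_mask(size, g$left$cx, g$left$cy, g$left$rx, g$left$ry) |
    ellipse_mask(size, g$right$cx, g$right$cy, g$right$rx, g$right$ry)
}

# Render one image (values in [0, 255]) plus a short parameter record.
render_cxr <- function(class, size, noise_sd) {
  g <- lung_geometry()
  img <- matrix(175, size, size)
  # brighter mediastinum band and shoulders
  xs <- (seq_len(size) - 0.5) / size
  band <- exp(-((xs - 0.5)^2) / (2 * 0.08^2))
  img <- img + matrix(40 * band, size, size, byrow = TRUE)
  top <- (seq_len(size) - 0.5) / size < 0.18
  img[top, ] <- img[top, ] + 25
  # dark lung fields
  lungs <- lung_field_mask(size)
  img[lungs] <- 70
  params <- sprintf("class=%s", class)
  if (class == "pneumonia") {
    side <- if (stats::runif(1) < 0.5) g$left else g$right
    cx <- side$cx + stats::runif(1, -0.05, 0.05)
    cy <- side$cy + stats::runif(1, -0.10, 0.10)
    img <- img + 110 * gaussian_bump(size, cx, cy, 0.07) * lungs
    params <- sprintf("%s;blob=(%.3f,%.3f)", params, cx, cy)
  } else if (class == "covid") {
    k <- sample(4:6, 1)
    centers <- character(k)
    for (i in seq_len(k)) {
      side <- if (i %% 2 == 0) g$left else g$right
      # peripheral zone: offset towards the outer half of the lung
      sgn <- if (identical(side, g$left)) -1 else 1
      cx <- side$cx + sgn * stats::runif(1, 0.05, 0.12)
      cy <- side$cy + stats::runif(1, -0.22, 0.22)
      img <- img + 45 * gaussian_bump(size, cx, cy, 0.045) * lungs
      centers[i] <- sprintf("(%.3f,%.3f)", cx, cy)
    }
    params <- sprintf("%s;n_opacity=%d;centers=%s", params, k,
                      paste(centers, collapse = "|"))
  }
  img <- img + matrix(stats::rnorm(size * size, sd = noise_sd), size, size)
  list(img = pmin(pmax(img, 0), 255), params = params)
}

image_seed <- function(master, class_idx, img_idx) {
  as.integer((as.double(master) * 100003 + class_idx * 10007 + img_idx) %% 2147483647)
}

#' Generate a synthetic chest-radiograph dataset on disk
#'
#' Writes 8-bit grayscale PNGs in a folder-per-class layout plus a
#' `manifest.csv` (`path,label,seed,params`). Deterministic: the same spec
#' produces byte-identical files.
#'
#' @param spec a [synthetic_spec()].
#' @param out_dir output directory (created if missing).
#' @return The manifest as a data frame, invisibly.
#' @export
generate_cxr_dataset <- function(spec, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(out_dir)) stop("unwritable output directory: ", out_dir)
  }
  rows <- vector("list", length(spec$classes) * spec$per_class)
  ri <- 0L
  for (ci in seq_along(spec$classes)) {
    cls <- spec$classes[ci]
    cls_dir <- file.path(out_dir, cls)
    dir.create(cls_dir, showWarnings = FALSE)
    for (i in seq_len(spec$per_class)) {
      sd_i <- image_seed(spec$seed, ci, i)
      r <- with_seed(sd_i, function() render_cxr(cls, spec$size, spec$noise_sd))
      path <- file.path(cls_dir, sprintf("%s_%04d.png", cls, i))
      png::writePNG(round(r$img) / 255, path)
      ri <- ri + 1L
      rows[[ri]] <- data.frame(path = path, label = cls, seed = sd_i,
                               params = r$params, stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

# ---- splitting ----------------------------------------------------------

# Largest-remainder apportionment of n into parts proportional to ratio.
apportion <- function(n, ratio) {
  if (any(ratio < 0)) stop("degenerate ratio: negative part")
  if (sum(ratio) <= 0) stop("degenerate ratio: all parts zero")
  quota <- n * ratio / sum(ratio)
  base <- floor(quota)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(quota - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Split a dataset into train/validation/test index sets
#'
#' Shuffles indices with the given seed and partitions them by
#' largest-remainder apportionment of the ratio. When `labels` are
#' supplied, the apportionment is applied within each class (stratified).
#'
#' @param n_items total number of items.
#' @param ratio three non-negative parts, e.g. `c(7, 2, 1)`.
#' @param seed integer shuffle seed.
#' @param labels optional per-item labels for stratification.
#' @return An object of class `split_indices`: list with integer vectors
#'   `train`, `val`, `test` (pairwise disjoint, covering `1:n_items`).
#' @export
split_dataset <- function(n_items, ratio = c(7, 2, 1), seed = 1L,
                          labels = NULL) {
  if (length(ratio) != 3L) stop("ratio must have three parts (train, val, test)")
  if (any(ratio < 0)) stop("degenerate ratio: negative part")
  if (n_items < sum(ratio > 0)) stop("n_items too small for the requested ratio")
  split_one <- function(idx) {
    perm <- with_seed(seed, function() sample(idx))
    sizes <- apportion(length(idx), ratio)
    list(train = perm[seq_len(sizes[1])],
         val = perm[sizes[1] + seq_len(sizes[2])],
         test = perm[sizes[1] + sizes[2] + seq_len(sizes[3])])
  }
  if (is.null(labels)) {
    parts <- split_one(seq_len(n_items))
  } else {
    if (length(labels) != n_items) stop("labels length must equal n_items")
    parts <- list(train = integer(0), val = integer(0), test = integer(0))
    for (cls in unique(labels)) {
      p <- split_one(which(labels == cls))
      parts$train <- c(parts$train, p$train)
      parts$val <- c(parts$val, p$val)
      parts$test <- c(parts$test, p$test)
    }
    parts <- lapply(parts, sort)
  }
  structure(parts, class = "split_indices")
}

# ---- loading ------------------------------------------------------------

#' Load and preprocess one image
#'
#' Decodes a PNG, converts to grayscale (BT.601 luma for color inputs),
#' bilinearly resizes to `size x size`, keeps values in [0, 1], and
#' replicates to three channels.
#'
#' @param path image file path.
#' @param size target square side (default 224).
#' @param standardize subtract the per-channel mean and divide by the
#'   per-channel standard deviation after resizing.
#' @return Array `3 x size x size`.
#' @export
load_and_preprocess <- function(path, size = 224L, standardize = FALSE) {
  img <- tryCatch(png::readPNG(path), error = function(e) {
    stop(sprintf("I/O error reading image '%s': %s", path, conditionMessage(e)))
  })
  if (length(dim(img)) == 3L) {
    nc <- dim(img)[3]
    img <- if (nc >= 3L) {
      0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
    } else img[, , 1]
  }
  if (!all(dim(img) == c(size, size))) {
    img <- EBImage::resize(img, w = size, h = size)
    img <- pmin(pmax(img, 0), 1)
  }
  out <- array(0, c(3L, size, size))
  for (ch in 1:3) out[ch, , ] <- img
  if (standardize) {
    mu <- mean(out[1, , ])
    sd_ <- stats::sd(out[1, , ])
    if (sd_ < 1e-8) sd_ <- 1
    out <- (out - mu) / sd_
  }
  out
}

#' Load a generated dataset into memory
#'
#' Reads every manifest row with [load_and_preprocess()] and stacks the
#' results into a batch array.
#'
#' @param manifest data frame with `path` and `label` columns (as written
#'   by [generate_cxr_dataset()]), or a dataset directory containing
#'   `manifest.csv`.
#' @param size target square side.
#' @param standardize forwarded to [load_and_preprocess()].
#' @return List with `x` (`N x 3 x size x size` array), `y` (integer class
#'   index, 1-based, ordered by [cxr_classes()]) and `classes`.
#' @export
load_cxr_dataset <- function(manifest, size = 64L, standardize = TRUE) {
  if (is.character(manifest)) {
    manifest <- utils::read.csv(file.path(manifest, "manifest.csv"),
                                stringsAsFactors = FALSE)
  }
  N <- nrow(manifest)
  x <- array(0, c(N, 3L, size, size))
  for (i in seq_len(N)) {
    x[i, , , ] <- load_and_preprocess(manifest$path[i], size, standardize)
  }
  classes <- cxr_classes()
  y <- match(manifest$label, classes)
  if (anyNA(y)) stop("manifest contains labels outside ", paste(classes, collapse = "/"))
  list(x = x, y = y, classes = classes)
}
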