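# Patch extraction, feature computation, and overlap-averaged reassembly.
#
# Patches are patch_size x patch_size squares addressed by their top-left
# pixel in 0-based (row, col) coordinates. The regular stride grid is
# augmented with a final flush row/column of patches so every pixel is
# covered without inventing border values. The learning target for a patch
# is the HD patch minus the mean of the co-located LD patch (its "dc"), so
# the model predicts detail residual on the LD baseline and the dc is added
# back at reassembly.

#' Patch extraction configuration
#'
#' @param patch_size Patch side length (default 8).
#' @param stride Grid stride, `1 <= stride <= patch_size` (default 2;
#'   inference typically uses stride 1 for dense overlap).
#' @param feature_mode `"gradient_filters"` (default): first-order central
#'   differences and second-order `[1, -2, 1]` responses in both axes,
#'   length `4 * patch_size^2`; or `"raw_dc_removed"`: the flattened patch
#'   minus its mean, length `patch_size^2`.
#' @param n_samples_cap Optional cap; a seeded uniform subsample of the
#'   extracted pairs is returned.
#' @param seed Integer seed (used only when subsampling).
#' @return A `patch_config` list.
#' @export
patch_config <- function(patch_size = 8, stride = 2,
                         feature_mode = c("gradient_filters", "raw_dc_removed"),
                         n_samples_cap = NULL, seed = 1) {
  feature_mode <- match.arg(feature_mode)
  if (patch_size < 1) stop_input("patch_size must be positive")
  if (stride < 1 || stride > patch_size) {
    stop_input("stride must satisfy 1 <= stride <= patch_size")
  }
  structure(list(patch_size = as.integer(patch_size),
                 stride = as.integer(stride), feature_mode = feature_mode,
                 n_samples_cap = n_samples_cap, seed = as.integer(seed)),
            class = "patch_config")
}

# 0-based grid positions along an axis of length n: regular stride grid plus
# a flush final position so coverage is complete.
grid_positions <- function(n, patch_size, stride) {
  last <- n - patch_size
  pos <- seq(0L, last, by = stride)
  if (pos[length(pos)] != last) pos <- c(pos, as.integer(last))
  pos
}

# Linear (column-major) pixel indices for every patch: n_patches x p^2.
# Patch pixel order is column-major within the patch, matching as.vector().
patch_indices <- function(h, w, patch_size, rows0, cols0) {
  p <- patch_size
  off <- as.vector(outer(seq_len(p) - 1L, (seq_len(p) - 1L) * h, "+"))
  start <- cols0 * h + rows0 + 1L
  outer(start, off, "+")
}

# Per-patch linear filter operators (4p^2 x p^2) for gradient_filters, with
# clamped (replicated) patch boundaries. Cached per patch size.
.filter_cache <- new.env(parent = emptyenv())

gradient_operator <- function(p) {
  key <- as.character(p)
  if (!is.null(.filter_cache[[key]])) return(.filter_cache[[key]])
  n <- p * p
  idx <- function(i, j) (j - 1L) * p + i          # column-major within patch
  clamp <- function(v) pmin(pmax(v, 1L), p)
  G <- matrix(0, 4L * n, n)
  for (j in seq_len(p)) {
    for (i in seq_len(p)) {
      r <- idx(i, j)
      # horizontal first-order central difference (along columns), /2
      G[r, idx(i, clamp(j + 1L))] <- G[r, idx(i, clamp(j + 1L))] + 0.5
      G[r, idx(i, clamp(j - 1L))] <- G[r, idx(i, clamp(j - 1L))] - 0.5
      # vertical first-order
      G[n + r, idx(clamp(i + 1L), j)] <- G[n + r, idx(clamp(i + 1L), j)] + 0.5
      G[n + r, idx(clamp(i - 1L), j)] <- G[n + r, idx(clamp(i - 1L), j)] - 0.5
      # horizontal second-order [1, -2, 1]
      G[2L * n + r, idx(i, clamp(j + 1L))] <- G[2L * n + r, idx(i, clamp(j + 1L))] + 1
      G[2L * n + r, idx(i, j)] <- G[2L * n + r, idx(i, j)] - 2
      G[2L * n + r, idx(i, clamp(j - 1L))] <- G[2L * n + r, idx(i, clamp(j - 1L))] + 1
      # vertical second-order
      G[3L * n + r, idx(clamp(i + 1L), j)] <- G[3L * n + r, idx(clamp(i + 1L), j)] + 1
      G[3L * n + r, idx(i, j)] <- G[3L * n + r, idx(i, j)] - 2
      G[3L * n + r, idx(clamp(i - 1L), j)] <- G[3L * n + r, idx(clamp(i - 1L), j)] + 1
    }
  }
  .filter_cache[[key]] <- G
  G
}

#' Compute the feature vector of a single patch
#'
#' @param patch A `patch_size x patch_size` numeric matrix.
#' @param feature_mode See [patch_config()].
#' @return A numeric feature vector (length `p^2` or `4 p^2`).
#' @export
compute_features <- function(patch, feature_mode = c("gradient_filters",
                                                     "raw_dc_removed")) {
  feature_mode <- match.arg(feature_mode)
  if (!is.matrix(patch) || nrow(patch) != ncol(patch)) {
    stop_input("patch must be a square matrix")
  }
  v <- as.vector(patch)
  if (feature_mode == "raw_dc_removed") v - mean(v)
  else as.vector(gradient_operator(nrow(patch)) %*% v)
}

# Batch feature computation for a raw-patch matrix X (n x p^2).
features_from_raw <- function(X, p, feature_mode) {
  if (feature_mode == "raw_dc_removed") X - rowMeans(X)
  else X %*% t(gradient_operator(p))
}

# Internal: extract patch positions, raw LD patch matrix, features and dc
# from a single image (used at training and inference).
extract_patches <- function(img, cfg) {
  px <- as_pixels(img)
  h <- nrow(px); w <- ncol(px)
  p <- cfg$patch_size
  if (p > min(h, w)) stop_input("patch_size exceeds image size")
  rows0 <- grid_positions(h, p, cfg$stride)
  cols0 <- grid_positions(w, p, cfg$stride)
  pos <- cbind(row = rep(rows0, times = length(cols0)),
               col = rep(cols0, each = length(rows0)))
  idx <- patch_indices(h, w, p, pos[, 1], pos[, 2])
  raw <- matrix(px[idx], nrow(idx), ncol(idx))
  list(positions = pos, raw = raw, dc = rowMeans(raw),
       features = features_from_raw(raw, p, cfg$feature_mode),
       index = idx, shape = c(h, w))
}

#' Extract paired training vectors from a registered LD/HD image pair
#'
#' Samples every grid position (regular stride grid plus flush border
#' patches); the target `x_H` is the HD patch minus the mean of the LD patch
#' at the same position. With `n_samples_cap` set, a seeded uniform
#' subsample is returned.
#'
#' @param ld,hd `ct_image`s of identical shape.
#' @param cfg A [patch_config()].
#' @return A `patch_pairs` object: list with `features` (n x D_L), `targets`
#'   (n x D_H), `dc` (length n), `positions` (n x 2, 0-based top-left),
#'   `patch_size`, `feature_mode`.
#' @export
extract_patch_pairs <- function(ld, hd, cfg = patch_config()) {
  check_same_shape(ld, hd)
  ex <- extract_patches(ld, cfg)
  hx <- as_pixels(hd)
  raw_hd <- matrix(hx[ex$index], nrow(ex$index), ncol(ex$index))
  targets <- raw_hd - ex$dc
  keep <- seq_len(nrow(targets))
  if (!is.null(cfg$n_samples_cap) && cfg$n_samples_cap < length(keep)) {
    keep <- withr::with_seed(cfg$seed,
                             sort(sample.int(length(keep), cfg$n_samples_cap)))
  }
  structure(list(features = ex$features[keep, , drop = FALSE],
                 targets = targets[keep, , drop = FALSE],
                 dc = ex$dc[keep],
                 positions = ex$positions[keep, , drop = FALSE],
                 patch_size = cfg$patch_size, feature_mode = cfg$feature_mode,
                 shape = ex$shape),
            class = "patch_pairs")
}

#' @export
print.patch_pairs <- function(x, ...) {
  cat(sprintf("<patch_pairs: %d pairs, patch %dx%d, %s features (D_L=%d, D_H=%d)>\n",
              nrow(x$features), x$patch_size, x$patch_size, x$feature_mode,
              ncol(x$features), ncol(x$targets)))
  invisible(x)
}

#' @export
length.patch_pairs <- function(x) nrow(x$features)

#' Reassemble an image from predicted patch details
#'
#' Each output pixel is the average over all covering patches of
#' `predicted detail + dc`, then clipped to `[0, peak]`.
#'
#' @param positions n x 2 matrix of 0-based top-left (row, col) positions.
#' @param predicted n x `p^2` matrix of predicted detail patches
#'   (column-major patch order).
#' @param dc Length-n vector of per-patch baselines to restore.
#' @param shape `c(height, width)` of the output image.
#' @param peak Peak intensity for clipping (default 255).
#' @return A `ct_image`.
#' @export
assemble_image <- function(positions, predicted, dc, shape, peak = 255) {
  p <- as.integer(sqrt(ncol(predicted)))
  if (p * p != ncol(predicted)) stop_input("predicted patches must be square")
  h <- shape[1]; w <- shape[2]
  idx <- patch_indices(h, w, p, positions[, 1], positions[, 2])
  acc <- numeric(h * w)
  cnt <- numeric(h * w)
  vals <- predicted + dc
  for (k in seq_len(ncol(idx))) {                 # p^2 vectorized scatters;
    ii <- idx[, k]                                # positions are unique so
    acc[ii] <- acc[ii] + vals[, k]                # indices never collide here
    cnt[ii] <- cnt[ii] + 1
  }
  if (any(cnt == 0)) stop_input("patch grid does not cover every pixel")
  ct_image(matrix(clip_range(acc / cnt, 0, peak), h, w), peak = peak)
}
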