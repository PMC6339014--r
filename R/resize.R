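# Separable bicubic (Keys cubic-convolution, a = -0.5) resampling with
# clamped borders. Used for the bicubic interpolation baseline; exact on
# constant and linear intensity fields.

keys_kernel <- function(t, a = -0.5) {
  t <- abs(t)
  w <- numeric(length(t))
  i1 <- t <= 1
  w[i1] <- (a + 2) * t[i1]^3 - (a + 3) * t[i1]^2 + 1
  i2 <- t > 1 & t < 2
  w[i2] <- a * t[i2]^3 - 5 * a * t[i2]^2 + 8 * a * t[i2] - 4 * a
  w
}

# 1-D cubic interpolation matrix mapping n_in samples to n_out samples
# (centre-aligned grids, clamped boundary).
cubic_matrix <- function(n_in, n_out) {
  scale <- n_in / n_out
  # centre-aligned grids: output sample i sits at input coordinate x
  x <- (seq_len(n_out) - 0.5) * scale + 0.5
  M <- matrix(0, n_out, n_in)
  base <- floor(x)
  for (k in -1:2) {
    j <- base + k
    wt <- keys_kernel(x - j)
    jc <- pmin(pmax(j, 1), n_in)
    for (i in seq_len(n_out)) M[i, jc[i]] <- M[i, jc[i]] + wt[i]
  }
  # kernel weights over 4 taps sum to 1 exactly, so rows already sum to 1
  M
}

#' Bicubic resampling of an image
#'
#' @param img A `ct_image` or matrix.
#' @param out_h,out_w Output dimensions.
#' @return A `ct_image` (values clipped to `[0, peak]`).
#' @export
resize_bicubic <- function(img, out_h, out_w) {
  px <- as_pixels(img)
  peak <- img_peak(img)
  Mr <- cubic_matrix(nrow(px), out_h)
  Mc <- cubic_matrix(ncol(px), out_w)
  out <- Mr %*% px %*% t(Mc)
  ct_image(clip_range(out, 0, peak), peak = peak)
}
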