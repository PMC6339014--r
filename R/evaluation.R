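# Image quality metrics: MSE, PSNR (255-peak), global SSIM.
#
# PSNR = 10 log10(255^2 / MSE) on the [0, 255] domain. SSIM is computed as a
# single global statistic per image pair with constants C1 = C2 = 1 by
# default (this package's operating convention; conventional windowed SSIM
# is available via mode = "windowed"). Variance and covariance use the
# population (1/N) convention.

#' Mean squared error between two images
#' @param orig,target `ct_image`s or matrices of identical shape.
#' @return Nonnegative scalar.
#' @export
mse <- function(orig, target) {
  check_same_shape(orig, target)
  mean((as_pixels(orig) - as_pixels(target))^2)
}

#' Peak signal-to-noise ratio in dB
#'
#' `10 * log10(255^2 / MSE)`. Identical images (MSE = 0) are reported as the
#' documented cap of 100 dB with attribute `zero_mse = TRUE` rather than
#' infinity.
#'
#' @inheritParams mse
#' @return PSNR in dB (scalar, possibly with attribute `zero_mse`).
#' @export
psnr <- function(orig, target) {
  m <- mse(orig, target)
  if (m == 0) return(structure(100, zero_mse = TRUE))
  min(10 * log10(255^2 / m), 100)
}

#' Structural similarity index
#'
#' Global mode (default) computes one statistic over the whole image pair:
#' `(2 ux uy + C1)(2 sxy + C2) / ((ux^2 + uy^2 + C1)(sx^2 + sy^2 + C2))`
#' with `C1 = C2 = 1`. Windowed mode averages the same statistic over 8x8
#' sliding windows (stride 1) for diagnostics.
#'
#' @param x,y Images of identical shape.
#' @param C1,C2 Stabilizing constants (default 1).
#' @param mode `"global"` or `"windowed"`.
#' @param window Window side for windowed mode (default 8).
#' @return SSIM value (in `[0, 1]` for nonnegative-intensity inputs).
#' @export
ssim <- function(x, y, C1 = 1, C2 = 1, mode = c("global", "windowed"),
                 window = 8) {
  mode <- match.arg(mode)
  check_same_shape(x, y)
  px <- as_pixels(x); py <- as_pixels(y)
  ssim_stat <- function(a, b) {
    ua <- mean(a); ub <- mean(b)
    va <- mean((a - ua)^2); vb <- mean((b - ub)^2)     # population variance
    cab <- mean((a - ua) * (b - ub))
    ((2 * ua * ub + C1) * (2 * cab + C2)) /
      ((ua^2 + ub^2 + C1) * (va + vb + C2))
  }
  if (mode == "global") return(ssim_stat(px, py))
  h <- nrow(px); w <- ncol(px)
  if (window > min(h, w)) stop_input("window exceeds image size")
  rows0 <- 0:(h - window); cols0 <- 0:(w - window)
  idx <- patch_indices(h, w, window,
                       rep(rows0, times = length(cols0)),
                       rep(cols0, each = length(rows0)))
  A <- matrix(px[idx], nrow(idx)); B <- matrix(py[idx], nrow(idx))
  ua <- rowMeans(A); ub <- rowMeans(B)
  va <- rowMeans(A^2) - ua^2; vb <- rowMeans(B^2) - ub^2
  cab <- rowMeans(A * B) - ua * ub
  mean(((2 * ua * ub + C1) * (2 * cab + C2)) /
         ((ua^2 + ub^2 + C1) * (va + vb + C2)))
}

#' Percentage improvement of a metric over a reference arm
#'
#' `100 * (new - ref) / ref`, the reporting convention used for PSNR/SSIM
#' comparisons (e.g. a PSNR pair 25.37 -> 35.94 dB is a 41.66% improvement).
#'
#' @param ref Reference value (e.g. baseline PSNR).
#' @param new Improved value.
#' @param digits Rounding for reporting (default 2).
#' @return Percentage (scalar).
#' @export
relative_improvement <- function(ref, new, digits = 2) {
  if (ref == 0) stop_input("reference value must be nonzero")
  round(100 * (new - ref) / ref, digits)
}

#' Extract one row of intensities for profile plots
#' @param img A `ct_image` or matrix.
#' @param row 0-based row index.
#' @return Numeric vector of length `width`.
#' @export
profile_line <- function(img, row) {
  px <- as_pixels(img)
  if (row < 0 || row >= nrow(px)) {
    stop_input("row must be in [0, ", nrow(px) - 1, "]")
  }
  px[row + 1L, ]
}

#' Residual image a - b
#' @param a,b Images of identical shape.
#' @return A matrix of signed differences.
#' @export
residual_image <- function(a, b) {
  check_same_shape(a, b)
  as_pixels(a) - as_pixels(b)
}

#' One metric-report row
#'
#' @param orig Reference (full-dose) image.
#' @param target Image under evaluation.
#' @param label Text tag of the compared arm.
#' @param C1,C2 SSIM constants.
#' @return A one-row tibble: `label`, `psnr_db`, `mse`, `ssim`, `zero_mse`.
#' @export
metric_report <- function(orig, target, label = "", C1 = 1, C2 = 1) {
  m <- mse(orig, target)
  p <- psnr(orig, target)
  tibble::tibble(label = label, psnr_db = as.numeric(p), mse = m,
                 ssim = ssim(orig, target, C1, C2),
                 zero_mse = isTRUE(attr(p, "zero_mse")))
}

#' Plot row profiles of several images
#'
#' @param images Named list of `ct_image`s.
#' @param row 0-based row index.
#' @return A ggplot object.
#' @export
plot_profiles <- function(images, row) {
  df <- dplyr::bind_rows(lapply(names(images), function(nm) {
    v <- profile_line(images[[nm]], row)
    tibble::tibble(arm = nm, col = seq_along(v), intensity = v)
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$intensity,
                                   colour = .data$arm)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "column", y = "intensity",
                  title = sprintf("Row %d profile", row))
}
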