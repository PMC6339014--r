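# Minimal parallel-beam Radon transform and filtered back-projection.
#
# Used only by the projection-domain dose degradation mode: forward-project
# the phantom, apply Poisson photon statistics to the transmission data,
# log-convert, and reconstruct. This is a deliberately small textbook
# implementation (rotate-and-sum forward model, Ram-Lak filtered
# back-projection with linear detector interpolation), not a scanner model.

# Bilinear rotation of a matrix about its centre; outside samples are `fill`.
rotate_bilinear <- function(mat, angle_deg, fill = 0) {
  h <- nrow(mat); w <- ncol(mat)
  th <- angle_deg * pi / 180
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  out_r <- rep(seq_len(h), times = w) - cy
  out_c <- rep(seq_len(w), each = h) - cx
  # inverse mapping: sample the source at the back-rotated coordinate
  src_c <- cos(th) * out_c - sin(th) * out_r + cx
  src_r <- sin(th) * out_c + cos(th) * out_r + cy
  r0 <- floor(src_r); c0 <- floor(src_c)
  fr <- src_r - r0;   fc <- src_c - c0
  val <- numeric(h * w)
  wts <- list(list(0, 0, (1 - fr) * (1 - fc)), list(1, 0, fr * (1 - fc)),
              list(0, 1, (1 - fr) * fc),       list(1, 1, fr * fc))
  for (wt in wts) {
    rr <- r0 + wt[[1]]; cc <- c0 + wt[[2]]
    ok <- rr >= 1 & rr <= h & cc >= 1 & cc <= w
    idx <- (cc[ok] - 1) * h + rr[ok]
    val[ok] <- val[ok] + wt[[3]][ok] * mat[idx]
  }
  val[is.na(val)] <- fill
  matrix(val, h, w)
}

# Forward parallel-beam projection: sinogram (detector x angle).
radon_transform <- function(px, angles_deg) {
  h <- nrow(px); w <- ncol(px)
  d <- ceiling(sqrt(2) * max(h, w))
  if ((d - max(h, w)) %% 2 == 1) d <- d + 1     # keep the centre aligned
  pad <- matrix(0, d, d)
  r0 <- (d - h) %/% 2; c0 <- (d - w) %/% 2
  pad[r0 + seq_len(h), c0 + seq_len(w)] <- px
  sino <- vapply(angles_deg,
                 function(a) colSums(rotate_bilinear(pad, a)),
                 numeric(d))
  attr(sino, "angles_deg") <- angles_deg
  sino                                           # d x n_angles
}

# Ram-Lak (ramp) filter applied per projection via FFT.
ramp_filter <- function(sino) {
  d <- nrow(sino)
  n <- 2^ceiling(log2(2 * d))
  freq <- c(seq(0, n / 2), seq(n / 2 - 1, 1)) / n   # |f| on the DFT grid
  out <- matrix(0, d, ncol(sino))
  for (j in seq_len(ncol(sino))) {
    p <- c(sino[, j], rep(0, n - d))
    f <- Re(stats::fft(stats::fft(p) * freq, inverse = TRUE)) / n
    out[, j] <- f[seq_len(d)]
  }
  out
}

# Filtered back-projection onto an out_h x out_w grid.
iradon_fbp <- function(sino, out_h, out_w) {
  d <- nrow(sino); n_ang <- ncol(sino)
  filt <- ramp_filter(sino)
  angles <- attr(sino, "angles_deg")
  cy <- (out_h + 1) / 2; cx <- (out_w + 1) / 2
  yy <- rep(seq_len(out_h), times = out_w) - cy
  xx <- rep(seq_len(out_w), each = out_h) - cx
  centre <- (d + 1) / 2
  acc <- numeric(out_h * out_w)
  for (j in seq_len(n_ang)) {
    th <- angles[j] * pi / 180
    # detector coordinate of each pixel for this view (matches colSums of the
    # back-rotated padded image in radon_transform)
    t <- cos(th) * xx + sin(th) * yy + centre
    t0 <- floor(t); ft <- t - t0
    v <- numeric(length(t))
    ok <- t0 >= 1 & t0 <= d
    v[ok] <- (1 - ft[ok]) * filt[t0[ok], j]
    ok2 <- t0 + 1 >= 1 & t0 + 1 <= d
    v[ok2] <- v[ok2] + ft[ok2] * filt[t0[ok2] + 1, j]
    acc <- acc + v
  }
  matrix(acc * pi / n_ang, out_h, out_w)   # angles span [0, pi)
}
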