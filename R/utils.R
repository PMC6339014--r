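# Internal helpers shared across modules.

# Clip values into [lo, hi].
clip_range <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Round half away from zero (for nonnegative intensities: round half up).
round_half_up <- function(x) floor(x + 0.5)

#' Derive a child seed from a master seed
#'
#' Deterministic integer mixing used everywhere a sub-computation (a tree, a
#' phantom, a noise draw) needs its own reproducible stream derived from one
#' master seed. Result is always in `[0, 2^31 - 2]`.
#'
#' @param seed Integer master seed.
#' @param k Integer stream index (which child).
#' @return A single integer seed.
#' @export
derive_seed <- function(seed, k) {
  s <- (abs(as.double(seed)) %% 2147483647)
  for (j in c(as.double(k) + 1, 7)) {
    s <- (s * 48271 + j * 8191 + 12345) %% 2147483647
  }
  as.integer(s)
}

stop_input <- function(...) stop(..., call. = FALSE)

check_same_shape <- function(a, b) {
  if (!identical(dim(as_pixels(a)), dim(as_pixels(b)))) {
    stop_input("images must have the same height and width")
  }
  invisible(TRUE)
}
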