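# Synthetic CT corpus: ellipse-composite phantoms and dose degradation.
#
# The generator stands in for a paired quarter-dose / full-dose clinical
# corpus: the full-dose ("HD") image is a piecewise-constant anatomical
# phantom, and the low-dose ("LD") partner is the same image degraded by a
# calibrated noise model. Both members of a pair are the same size
# (restoration framing).

#' Specification of a synthetic ellipse phantom
#'
#' @param size Side length of the square image (pixels, `>= 32`).
#' @param n_ellipses Number of interior ellipses (`>= 1`).
#' @param intensity_range Length-2 numeric in `[0, 255]`: interior ellipse
#'   intensities are drawn uniformly from this range.
#' @param seed Integer seed; phantoms are fully determined by this object.
#' @param body_intensity Intensity of the body (soft-tissue) ellipse.
#' @param gradient_amplitude Peak amplitude of the mild smooth background
#'   gradient added inside the body (intensity units).
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(size = 128, n_ellipses = 4,
                         intensity_range = c(60, 200), seed = 1,
                         body_intensity = 40, gradient_amplitude = 2) {
  if (size < 32) stop_input("phantom size must be >= 32")
  if (n_ellipses < 1) stop_input("n_ellipses must be >= 1")
  if (length(intensity_range) != 2 || any(intensity_range < 0) ||
      any(intensity_range > 255) ||
      intensity_range[2] < intensity_range[1]) {
    stop_input("intensity_range must be an increasing pair within [0, 255]")
  }
  structure(list(size = as.integer(size), n_ellipses = as.integer(n_ellipses),
                 intensity_range = as.numeric(intensity_range),
                 seed = as.integer(seed),
                 body_intensity = body_intensity,
                 gradient_amplitude = gradient_amplitude),
            class = "phantom_spec")
}

#' Noise model for dose degradation
#'
#' `image_gaussian` adds zero-mean Gaussian noise of standard deviation
#' `base_sigma / sqrt(dose_fraction)` and clips to `[0, 255]` — the quantum
#' noise scaling under which quarter dose doubles the noise std.
#' `projection_poisson` forward-projects the image, applies Poisson photon
#' statistics at `incident_counts * dose_fraction` photons per detector bin,
#' log-converts and reconstructs by filtered back-projection, producing
#' correlated streak-like noise.
#'
#' @param dose_fraction Fraction of full dose in `(0, 1]` (default 0.25,
#'   i.e. quarter dose).
#' @param mode `"image_gaussian"` or `"projection_poisson"`.
#' @param base_sigma Gaussian std at full dose, intensity units.
#' @param incident_counts Photons per detector bin at full dose.
#' @param n_angles Number of projection angles (projection mode).
#' @param seed Integer seed.
#' @return A `dose_model` list.
#' @export
dose_model <- function(dose_fraction = 0.25,
                       mode = c("image_gaussian", "projection_poisson"),
                       base_sigma = 5, incident_counts = 2e5,
                       n_angles = 180, seed = 1) {
  mode <- match.arg(mode)
  if (!is.numeric(dose_fraction) || dose_fraction <= 0 || dose_fraction > 1) {
    stop_input("dose_fraction must be in (0, 1]")
  }
  if (base_sigma < 0) stop_input("base_sigma must be nonnegative")
  if (incident_counts <= 0) stop_input("incident_counts must be positive")
  structure(list(dose_fraction = dose_fraction, mode = mode,
                 base_sigma = base_sigma, incident_counts = incident_counts,
                 n_angles = as.integer(n_angles), seed = as.integer(seed)),
            class = "dose_model")
}

ellipse_mask <- function(size, cx, cy, a, b, theta) {
  u <- (seq_len(size) - (size + 1) / 2) / (size / 2)   # [-1, 1] coords
  X <- matrix(rep(u, each = size), size, size)          # column coord
  Y <- matrix(rep(u, times = size), size, size)         # row coord
  xr <- cos(theta) * (X - cx) + sin(theta) * (Y - cy)
  yr <- -sin(theta) * (X - cx) + cos(theta) * (Y - cy)
  (xr / a)^2 + (yr / b)^2 <= 1
}

#' Generate a synthetic CT phantom
#'
#' A body ellipse containing `n_ellipses` interior ellipses with distinct
#' intensities, plus a mild smooth intensity gradient inside the body.
#' Deterministic given `spec$seed`. The region masks used by the generator
#' are attached as attribute `"masks"` (`body` plus one mask per interior
#' ellipse) so tests can interrogate ground-truth regions.
#'
#' @param spec A [phantom_spec()].
#' @return A `ct_image` with pixels in `[0, 255]`.
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  s <- spec$size
  withr::with_seed(spec$seed, {
    body <- ellipse_mask(s, 0, 0, 0.88, 0.75, 0)
    px <- matrix(0, s, s)
    px[body] <- spec$body_intensity
    # mild smooth gradient confined to the body
    dir <- stats::runif(1, 0, 2 * pi)
    u <- (seq_len(s) - (s + 1) / 2) / (s / 2)
    X <- matrix(rep(u, each = s), s, s)
    Y <- matrix(rep(u, times = s), s, s)
    grad <- spec$gradient_amplitude * (cos(dir) * X + sin(dir) * Y)
    px[body] <- px[body] + grad[body]
    masks <- list(body = body)
    for (i in seq_len(spec$n_ellipses)) {
      cx <- stats::runif(1, -0.45, 0.45)
      cy <- stats::runif(1, -0.35, 0.35)
      a <- stats::runif(1, 0.08, 0.28)
      b <- stats::runif(1, 0.08, 0.28)
      th <- stats::runif(1, 0, pi)
      val <- stats::runif(1, spec$intensity_range[1], spec$intensity_range[2])
      m <- ellipse_mask(s, cx, cy, a, b, th) & body
      px[m] <- val + grad[m]
      masks[[paste0("ellipse_", i)]] <- m
    }
    img <- ct_image(clip_range(px, 0, 255))
    attr(img, "masks") <- masks
    img
  })
}

#' Degrade a full-dose image to a simulated low-dose acquisition
#'
#' @param hd A `ct_image` normalized to `[0, 255]`.
#' @param dose A [dose_model()].
#' @return A `ct_image`, same shape as `hd`, pixels in `[0, 255]`.
#' @export
simulate_low_dose <- function(hd, dose) {
  stopifnot(inherits(dose, "dose_model"))
  px <- as_pixels(hd)
  peak <- img_peak(hd)
  out <- withr::with_seed(dose$seed, {
    if (dose$mode == "image_gaussian") {
      sigma <- dose$base_sigma / sqrt(dose$dose_fraction)
      if (sigma == 0) px else px + matrix(stats::rnorm(length(px), 0, sigma),
                                          nrow(px))
    } else {
      angles <- seq(0, 180, length.out = dose$n_angles + 1)[seq_len(dose$n_angles)]
      sino <- radon_transform(px, angles)
      # map line integrals to attenuation so the densest ray transmits ~2%
      scale <- max(sino) / 4
      i0 <- dose$incident_counts * dose$dose_fraction
      counts <- stats::rpois(length(sino), i0 * exp(-sino / scale))
      counts <- pmax(counts, 0.5)                 # guard the log at zero counts
      sino_hat <- matrix(-scale * log(counts / i0), nrow(sino))
      attr(sino_hat, "angles_deg") <- angles
      iradon_fbp(sino_hat, nrow(px), ncol(px))
    }
  })
  ct_image(clip_range(out, 0, peak), peak = peak)
}

#' Generate a paired low-dose / full-dose training corpus
#'
#' Per-pair seeds are derived deterministically from the master seeds in
#' `spec` and `dose`, so the whole corpus is reproducible from the two
#' specification objects.
#'
#' @param n_pairs Number of image pairs (`>= 1`).
#' @param spec A [phantom_spec()]; each pair uses a derived seed.
#' @param dose A [dose_model()]; each pair uses a derived seed.
#' @return A list of `n_pairs` elements, each `list(ld = , hd = )`.
#' @export
make_training_set <- function(n_pairs, spec = phantom_spec(),
                              dose = dose_model()) {
  if (n_pairs < 1) stop_input("n_pairs must be >= 1")
  lapply(seq_len(n_pairs), function(i) {
    sp <- spec; sp$seed <- derive_seed(spec$seed, i)
    dm <- dose; dm$seed <- derive_seed(dose$seed, i + 100000L)
    hd <- make_phantom(sp)
    attr(hd, "masks") <- NULL
    list(ld = simulate_low_dose(hd, dm), hd = hd)
  })
}
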