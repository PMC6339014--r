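# Shared fixtures, all generated in code.

# Small ramp image: value = row + col (0-based), useful for exact checks.
ramp_image <- function(h = 16, w = 16, scale = 1) {
  ct_image(outer(seq_len(h) - 1, seq_len(w) - 1, "+") * scale)
}

# Seeded random 8-bit image.
random_image <- function(h = 12, w = 12, seed = 1) {
  withr::with_seed(seed, ct_image(matrix(sample(0:255, h * w, TRUE), h, w)))
}

# Tiny registered corpus for fast pipeline tests.
tiny_corpus <- function(n = 2, size = 48, seed = 5, sigma = 5) {
  make_training_set(n, phantom_spec(size = size, n_ellipses = 2, seed = seed),
                    dose_model(base_sigma = sigma, seed = seed + 50))
}

# Fast pipeline config for smoke-level training.
tiny_pipeline_config <- function(seed = 9, dict_enabled = FALSE) {
  pipeline_config(
    forest = forest_config(n_trees = 2, max_depth = 4, min_leaf_samples = 40,
                           seed = seed),
    patch = patch_config(patch_size = 6, stride = 3, n_samples_cap = 1500,
                         seed = seed),
    dict = dict_config(enabled = dict_enabled, B = 32, n_iter = 4,
                       max_train_cols = 400, clean_iter = 10),
    n_iterations = 2, seed = seed
  )
}

# Random orthonormal dictionary of dimension d (square).
orthonormal_dictionary <- function(d, seed = 1) {
  Q <- withr::with_seed(seed, qr.Q(qr(matrix(rnorm(d * d), d, d))))
  dictionary(Q, normalized = TRUE)
}

expect_images_equal <- function(a, b, tol = 1e-9) {
  expect_lt(max(abs(as_pixels(a) - as_pixels(b))), tol)
}

as_pixels <- rfctsr:::as_pixels
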