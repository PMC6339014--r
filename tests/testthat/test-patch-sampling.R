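test_that("grid counts match the closed-form enumeration", {
  img <- ramp_image(8, 8)
  pp <- extract_patch_pairs(img, img, patch_config(patch_size = 8, stride = 2))
  expect_equal(length(pp), 1L)

  img16 <- ramp_image(16, 16)
  pp9 <- extract_patch_pairs(img16, img16,
                             patch_config(patch_size = 8, stride = 4))
  expect_equal(length(pp9), 9L)                     # positions 0, 4, 8 per axis
  expect_setequal(unique(pp9$positions[, 1]), c(0, 4, 8))

  # flush border patch is appended when the stride misses the edge
  grid_count <- function(n, p, s) {
    reg <- length(seq(0, n - p, by = s))
    reg + as.integer((n - p) %% s != 0)
  }
  for (case in list(c(17, 8, 2), c(21, 6, 4), c(33, 8, 3), c(16, 8, 8))) {
    img_c <- ramp_image(case[1], case[1])
    pp_c <- extract_patch_pairs(img_c, img_c,
                                patch_config(case[2], case[3]))
    expect_equal(length(pp_c), grid_count(case[1], case[2], case[3])^2)
  }
})

test_that("identity pairs give DC-removed targets and capped sampling is seeded", {
  img <- random_image(20, 20, seed = 8)
  pp <- extract_patch_pairs(img, img,
                            patch_config(8, 4, "raw_dc_removed"))
  # x_H equals the DC-removed raw LD patch, and has zero mean
  expect_lt(max(abs(pp$targets - pp$features)), 1e-12)
  expect_lt(max(abs(rowMeans(pp$targets))), 1e-9)

  cfg_cap <- patch_config(8, 2, n_samples_cap = 10, seed = 3)
  a <- extract_patch_pairs(img, img, cfg_cap)
  b <- extract_patch_pairs(img, img, cfg_cap)
  expect_equal(length(a), 10L)
  expect_identical(a$positions, b$positions)

  expect_error(extract_patch_pairs(img, ramp_image(8, 8)), "same")
})

test_that("feature filters annihilate constants and recover ramp slopes", {
  const <- matrix(7, 8, 8)
  expect_equal(compute_features(const, "raw_dc_removed"), rep(0, 64))
  expect_equal(compute_features(const, "gradient_filters"), rep(0, 256))

  # horizontal ramp with slope 3 per column: interior horizontal first-order
  # response is the slope; vertical responses vanish everywhere
  slope <- 3
  ramp <- matrix(rep(slope * (0:7), each = 8), 8, 8)
  f <- compute_features(ramp, "gradient_filters")
  gx <- matrix(f[1:64], 8, 8)
  gy <- matrix(f[65:128], 8, 8)
  expect_equal(gx[, 2:7], matrix(slope, 8, 6))
  expect_equal(gy, matrix(0, 8, 8))
  # second-order responses vanish in the interior of a linear ramp
  gxx <- matrix(f[129:192], 8, 8)
  expect_equal(gxx[, 2:7], matrix(0, 8, 6))

  # batch path agrees with the per-patch path
  img <- random_image(12, 12, seed = 2)
  pp <- extract_patch_pairs(img, img, patch_config(6, 3))
  for (i in c(1, nrow(pp$positions))) {
    r <- pp$positions[i, 1] + 1; c <- pp$positions[i, 2] + 1
    patch <- img$pixels[r:(r + 5), c:(c + 5)]
    expect_equal(as.vector(pp$features[i, ]),
                 compute_features(patch, "gradient_filters"))
  }
})

test_that("extract -> assemble with identity predictions reproduces the image", {
  for (seed in c(1, 4)) {
    img <- random_image(19, 23, seed = seed)
    cfg <- patch_config(6, 2, "raw_dc_removed")
    pp <- extract_patch_pairs(img, img, cfg)
    out <- assemble_image(pp$positions, pp$targets, pp$dc, dim(img))
    expect_images_equal(out, img, tol = 1e-9)
  }

  # single full-image patch: output is patch + dc
  img8 <- random_image(8, 8, seed = 6)
  pp1 <- extract_patch_pairs(img8, img8, patch_config(8, 8, "raw_dc_removed"))
  out1 <- assemble_image(pp1$positions, pp1$targets, pp1$dc, c(8, 8))
  expect_images_equal(out1, img8)
})

test_that("overlap averaging matches a brute-force accumulator", {
  h <- 10; w <- 10; p <- 4
  positions <- rbind(c(0, 0), c(2, 2), c(4, 4), c(6, 6), c(0, 6), c(6, 0),
                     c(3, 0), c(0, 3), c(6, 3), c(3, 6), c(3, 3))
  preds <- matrix(rep(seq_len(nrow(positions)) * 10, p * p),
                  nrow(positions))                  # constant per patch
  dc <- rep(0, nrow(positions))
  acc <- matrix(0, h, w); cnt <- matrix(0, h, w)
  for (i in seq_len(nrow(positions))) {
    rr <- positions[i, 1] + 1:p; cc <- positions[i, 2] + 1:p
    acc[rr, cc] <- acc[rr, cc] + preds[i, 1]
    cnt[rr, cc] <- cnt[rr, cc] + 1
  }
  expect_true(all(cnt > 0))                         # full coverage by design
  out <- assemble_image(positions, preds, dc, c(h, w))
  expect_equal(out$pixels, pmin(acc / cnt, 255), tolerance = 1e-12)

  # uncovered pixels are an error
  expect_error(assemble_image(rbind(c(0, 0)), preds[1, , drop = FALSE],
                              0, c(h, w)),
               "cover")
})
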