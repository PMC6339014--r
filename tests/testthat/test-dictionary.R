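test_that("sparse coding matches the soft-threshold closed form on orthonormal D", {
  for (seed in 1:8) {
    d <- 12
    D <- orthonormal_dictionary(d, seed = seed)
    x <- withr::with_seed(100 + seed, rnorm(d))
    lam <- c(0, 0.05, 0.3, 1)[(seed %% 4) + 1]
    code <- sparse_code(x, D, lambda = lam, max_iter = 500, tol = 0)
    z <- crossprod(D$atoms, x)
    closed <- sign(z) * pmax(abs(z) - lam / 2, 0)
    expect_lt(max(abs(code$alpha - closed)), 1e-6)
    if (lam == 0) expect_lt(sqrt(sum((x - D$atoms %*% code$alpha)^2)), 1e-9)
  }
})

test_that("objective trace is monotone and the nnz field counts support", {
  D <- orthonormal_dictionary(10, seed = 3)
  x <- withr::with_seed(9, rnorm(10))
  code <- sparse_code(x, D, lambda = 0.5, max_iter = 100)
  expect_true(all(diff(code$objective) <= 1e-10))
  expect_equal(code$nnz, sum(abs(code$alpha) > 1e-12))
})

test_that("a single-atom signal concentrates its code on that atom", {
  D <- orthonormal_dictionary(16, seed = 5)
  x <- 3 * D$atoms[, 5]
  code <- sparse_code(x, D, lambda = 0.01, max_iter = 300, tol = 0)
  expect_equal(code$alpha[5], 3, tolerance = 0.01)
  expect_lt(max(abs(code$alpha[-5])), 0.01)
})

test_that("sparse coding agrees with an independent lasso solver", {
  skip_if_not_installed("glmnet")
  set.seed(21)
  d <- 20; B <- 30
  atoms <- matrix(rnorm(d * B), d, B)
  D <- normalize_dictionary(dictionary(atoms))
  x <- rnorm(d)
  lam <- 0.4
  code <- sparse_code(x, D, lambda = lam, max_iter = 5000, tol = 0)
  # glmnet minimizes 1/(2n) ||x - D a||^2 + s ||a||_1  ->  s = lam / (2 d)
  fit <- glmnet::glmnet(D$atoms, x, lambda = lam / (2 * d), intercept = FALSE,
                        standardize = FALSE, thresh = 1e-14)
  expect_lt(max(abs(code$alpha - as.vector(fit$beta))), 1e-4)
})

test_that("reconstruct_from_code is the dictionary-atom combination", {
  D <- orthonormal_dictionary(8, seed = 2)
  e3 <- numeric(8); e3[3] <- 1
  expect_equal(reconstruct_from_code(D, e3), D$atoms[, 3])
  expect_equal(reconstruct_from_code(D, numeric(8)), numeric(8))
  a <- withr::with_seed(4, rnorm(8))
  expect_equal(reconstruct_from_code(D, a), as.vector(D$atoms %*% a))
})

test_that("backproject reduces to sparse_code for identity H and is consistent
           through blur-downsample", {
  D <- orthonormal_dictionary(16, seed = 7)
  y <- withr::with_seed(8, rnorm(16))
  a <- sparse_code(y, D, lambda = 0.2, max_iter = 60, tol = 1e-12)
  b <- backproject(y, D, degradation_operator("identity"), lambda = 0.2,
                   max_iter = 60, tol = 1e-12)
  expect_identical(a$alpha, b$alpha)

  # H = blur + downsample by 2 on a signal synthesized as H(D alpha*)
  H <- degradation_operator("blur_downsample", factor = 2)
  Hm <- rfctsr:::degradation_matrix(H, 16)
  expect_equal(dim(Hm), c(4L, 16L))
  astar <- numeric(16); astar[c(2, 9)] <- c(1.5, -2)
  yobs <- as.vector(Hm %*% (D$atoms %*% astar))
  rec <- backproject(yobs, D, H, lambda = 1e-8, max_iter = 3000, tol = 0)
  expect_lt(sqrt(sum((Hm %*% (D$atoms %*% rec$alpha) - yobs)^2)), 1e-6)

  # full-shrinkage limit
  big <- backproject(y, D, lambda = 1e6, max_iter = 50)
  expect_equal(big$alpha, numeric(16))
  expect_error(backproject(rnorm(5), D), "dimension")
})

test_that("coupled learning descends its objective and recovers planted atoms", {
  # descent + n_iter = 0 contract
  set.seed(31)
  XL <- matrix(rnorm(12 * 60), 12, 60)
  fit0 <- learn_coupled_dicts(XL, XL, B = 8, lambda = 0.05, n_iter = 0,
                              seed = 2)
  expect_equal(fit0$E, matrix(0, 8, 60))
  fit <- learn_coupled_dicts(XL, XL, B = 8, lambda = 0.05, n_iter = 6,
                             seed = 2)
  expect_true(all(diff(fit$objective) <= 1e-8))
  expect_lte(fit$objective[length(fit$objective)], fit$objective[1])

  # planted model: B = 8 atoms, 1-sparse codes, no noise
  set.seed(32)
  d <- 16; B <- 8; N <- 240
  Dstar <- qr.Q(qr(matrix(rnorm(d * d), d, d)))[, 1:B]
  which_atom <- sample.int(B, N, replace = TRUE)
  coef <- runif(N, 1, 3) * sample(c(-1, 1), N, replace = TRUE)
  X <- Dstar[, which_atom] * rep(coef, each = d)
  out <- learn_coupled_dicts(X, X, B = B, lambda = 0.02, n_iter = 30,
                             seed = 5, coding_iter = 40)
  Dj <- out$joint$atoms
  Dj <- sweep(Dj, 2, pmax(sqrt(colSums(Dj^2)), 1e-12), "/")
  # matching against planted directions: every planted atom must have a
  # learned atom with |cosine| > 0.99
  planted_joint <- rbind(Dstar / sqrt(d), Dstar / sqrt(d))
  planted_joint <- sweep(planted_joint, 2,
                         sqrt(colSums(planted_joint^2)), "/")
  corr <- abs(crossprod(planted_joint, Dj))
  expect_true(all(apply(corr, 1, max) > 0.99))

  expect_warning(learn_coupled_dicts(X[, 1:4], X[, 1:4], B = 8, n_iter = 1),
                 "replacement")
})

test_that("normalized dictionaries have unit columns and gates are enforced", {
  set.seed(41)
  D <- dictionary(matrix(rnorm(40), 8, 5))
  Dn <- normalize_dictionary(D)
  expect_equal(colSums(Dn$atoms^2), rep(1, 5), tolerance = 1e-12)
  expect_error(sparse_code(rnorm(8), D), "normalized")
  expect_error(sparse_code(c(NA, rnorm(7)), Dn), "finite")
})
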