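# Independent oracle for the ridge solve: QR on the augmented system
# [Psi; sqrt(eta) I] W^T = [X_H; 0], a different numerical route than the
# normal-equation solve used by fit_leaf_model.
ridge_oracle <- function(Psi, XH, eta) {
  P <- ncol(Psi)
  A <- rbind(Psi, sqrt(eta) * diag(P))
  B <- rbind(XH, matrix(0, P, ncol(XH)))
  t(qr.solve(A, B))
}

test_that("basis expansion matches elementwise powers", {
  expect_equal(basis_expand(c(2, 3), basis_spec("linear", 1)), c(1, 2, 3))
  expect_equal(basis_expand(2, basis_spec("polynomial", 2)), c(1, 2, 4))
  expect_equal(basis_expand(c(5, -1), basis_spec("polynomial", 0)), 1)
  expect_equal(basis_expand(c(1, 2), basis_spec("linear", 1,
                                                includes_constant = FALSE)),
               c(1, 2))
  X <- matrix(1:6, 3, 2)
  expect_equal(basis_expand(X, basis_spec("polynomial", 2)),
               cbind(1, X, X^2))
})

test_that("ridge leaf solution matches the augmented-QR oracle on 50 instances", {
  for (seed in 1:50) {
    set.seed(seed)
    n <- sample(10:40, 1); d <- sample(2:5, 1); q <- sample(1:3, 1)
    eta <- 10^runif(1, -4, 0)
    XL <- matrix(rnorm(n * d), n, d)
    XH <- matrix(rnorm(n * q), n, q)
    leaf <- fit_leaf_model(XL, XH, basis_spec(), eta)
    Psi <- basis_expand(XL, basis_spec())
    W0 <- ridge_oracle(Psi, XH, eta)
    expect_lt(max(abs(leaf$W - W0)), 1e-6)
    # normal equations residual
    resid <- (crossprod(Psi) + eta * diag(ncol(Psi))) %*% t(leaf$W) -
      crossprod(Psi, XH)
    expect_lt(max(abs(resid)), 1e-6)
  }
})

test_that("ridge limits: exact recovery as eta -> 0, shrinkage as eta -> Inf", {
  set.seed(2)
  A <- matrix(rnorm(2 * 4), 2, 4)                   # targets = A Psi
  XL <- matrix(rnorm(30 * 3), 30, 3)
  Psi <- basis_expand(XL, basis_spec())
  XH <- Psi %*% t(A)
  leaf <- fit_leaf_model(XL, XH, basis_spec(), ridge = 1e-10)
  expect_lt(max(abs(leaf$W - A)), 1e-6)
  big <- fit_leaf_model(XL, XH, basis_spec(), ridge = 1e12)
  expect_lt(max(abs(big$W)), 1e-6)
})

test_that("split response thresholds with equality routed to the right branch", {
  expect_equal(split_response(5, list(feature_index = 0L, threshold = 5)), 1L)
  expect_equal(split_response(4.9, list(feature_index = 0L, threshold = 5)), 0L)
  expect_equal(split_response(c(3, 1),
                              list(feature_index = 0L,
                                   second_feature_index = 1L, threshold = 1)),
               1L)                                   # r = 3 - 1 - 1 = 1 >= 0
  expect_equal(split_response(c(3, 1),
                              list(feature_index = 0L,
                                   second_feature_index = 1L, threshold = 2.5)),
               0L)
  expect_error(split_response(c(1, 2), list(feature_index = 5L,
                                            threshold = 0)), "range")
})

test_that("node purity combines label residual and data scatter", {
  # identical, perfectly fit samples have zero purity
  XL <- matrix(1, 5, 2); XH <- matrix(2, 5, 3)
  expect_equal(node_purity(XL, XH, k = 1, predictor = "mean"), 0)

  # k = 0 leaves only the mean squared prediction residual
  set.seed(3)
  XL <- matrix(rnorm(12), 6, 2); XH <- matrix(rnorm(18), 6, 3)
  pm <- node_purity(XL, XH, k = 0, predictor = "mean")
  expect_equal(pm, mean(rowSums(sweep(XH, 2, colMeans(XH))^2)))

  # term-by-term arithmetic on a fixed 1-D instance with the ridge predictor
  xl <- matrix(c(0, 1, 2)); xh <- matrix(c(0.5, 1.0, 2.5))
  eta <- 0.01
  purity <- node_purity(xl, xh, k = 2, ridge = eta)
  Psi <- cbind(1, xl)
  W <- t(solve(crossprod(Psi) + eta * diag(2), crossprod(Psi, xh)))
  resid <- xh - Psi %*% t(W)
  expected <- mean(resid^2) + 2 * mean((xl - mean(xl))^2)
  expect_equal(purity, expected, tolerance = 1e-10)

  expect_error(node_purity(matrix(nrow = 0, ncol = 1),
                           matrix(nrow = 0, ncol = 1)), "empty")
})

test_that("split quality separates separable clusters and rejects tiny children", {
  XL <- matrix(c(rep(0, 6), rep(10, 6)), ncol = 1)
  XH <- matrix(c(rep(-1, 6), rep(1, 6)), ncol = 1)
  good <- list(feature_index = 0L, threshold = 5)
  bad <- list(feature_index = 0L, threshold = -1)   # all right: inadmissible
  expect_equal(split_quality(good, XL, XH, k = 1, min_leaf = 2), 0)
  expect_identical(split_quality(bad, XL, XH, min_leaf = 2), Inf)
  mixing <- list(feature_index = 0L, threshold = 10)  # 6 left+6 right? r=0 -> right
  expect_gt(split_quality(list(feature_index = 0L, threshold = 0.5),
                          XL, XH, k = 1, min_leaf = 2), -1)
})

test_that("vectorized split scores agree with per-candidate split_quality", {
  set.seed(11)
  XL <- matrix(rnorm(60 * 3), 60, 3)
  XH <- XL[, 1:2] + 0.1 * matrix(rnorm(120), 60, 2)
  cand <- rfctsr:::draw_split_candidates(XL, 25, "single", seed = 4)
  sc <- rfctsr:::score_candidates(XL, XH, cand, k = 1, min_leaf = 5)
  for (j in seq_len(nrow(cand))) {
    theta <- list(feature_index = cand$feature_index[j],
                  second_feature_index = cand$second_feature_index[j],
                  threshold = cand$threshold[j])
    q <- split_quality(theta, XL, XH, k = 1, min_leaf = 5, predictor = "mean")
    if (is.finite(q)) expect_equal(sc$Q[j], q, tolerance = 1e-8)
    else expect_identical(sc$Q[j], Inf)
  }
})

test_that("the root split attains the exhaustive minimum over its candidates", {
  for (seed in c(3, 17, 42)) {
    set.seed(seed)
    n <- 180
    XL <- matrix(rnorm(n), ncol = 1)
    XH <- matrix(sign(XL) + 0.2 * rnorm(n), ncol = 1)
    cfg <- forest_config(max_depth = 3, min_leaf_samples = 10,
                         n_candidate_splits = 30, seed = seed)
    tree <- grow_tree(list(features = XL, targets = XH), cfg,
                      rng_seed = seed, record_root = TRUE)
    cand <- attr(tree, "root_candidates")
    expect_false(is.null(cand))
    qs <- vapply(seq_len(nrow(cand)), function(j) {
      theta <- list(feature_index = cand$feature_index[j],
                    second_feature_index = cand$second_feature_index[j],
                    threshold = cand$threshold[j])
      split_quality(theta, XL, XH, k = cfg$split_reg, min_leaf = 10,
                    predictor = "mean")
    }, numeric(1))
    expect_equal(min(qs), min(cand$quality), tolerance = 1e-8)
    expect_equal(tree$threshold, cand$threshold[which.min(cand$quality)])
    expect_equal(tree$feature_index,
                 cand$feature_index[which.min(cand$quality)])
  }
})

test_that("trees recover piecewise structure and obey structural invariants", {
  # depth-0 tree is the global ridge model
  set.seed(5)
  XL <- matrix(rnorm(100 * 2), 100, 2)
  XH <- matrix(rnorm(100), 100, 1)
  t0 <- grow_tree(list(features = XL, targets = XH),
                  forest_config(max_depth = 0, min_leaf_samples = 10))
  expect_identical(t0$type, "leaf")
  glob <- fit_leaf_model(XL, XH, basis_spec(), 0.01)
  expect_equal(t0$W, glob$W)

  # piecewise data: split in the gap, leaves predict the two levels
  set.seed(6)
  x <- c(runif(100, -2, -0.5), runif(100, 0.5, 2))
  y <- c(rep(-1, 100), rep(1, 100)) + 0.01 * rnorm(200)
  tree <- grow_tree(list(features = matrix(x), targets = matrix(y)),
                    forest_config(max_depth = 1, min_leaf_samples = 20,
                                  split_reg = 0, seed = 2),
                    basis_spec("polynomial", 0))
  expect_identical(tree$type, "split")
  expect_gt(tree$threshold, -0.5)
  expect_lt(tree$threshold, 0.5)
  expect_equal(tree$left$W[1, 1], -1, tolerance = 0.05)
  expect_equal(tree$right$W[1, 1], 1, tolerance = 0.05)

  # structural invariants on randomized inputs
  set.seed(7)
  XL <- matrix(rnorm(400 * 3), 400, 3)
  XH <- matrix(rnorm(400 * 2), 400, 2)
  cfg <- forest_config(max_depth = 4, min_leaf_samples = 25, seed = 3)
  tr <- grow_tree(list(features = XL, targets = XH), cfg)
  leaves <- rfctsr:::walk_leaves(tr, function(l) {
    expect_gte(l$n_train, 25)
    expect_lte(l$depth, 4)
    l$n_train
  })
  expect_gte(length(leaves), 1)
})

test_that("forests are deterministic, average their trees, and T=1 is a tree", {
  set.seed(8)
  XL <- matrix(rnorm(200 * 2), 200, 2)
  XH <- matrix(XL[, 1] - XL[, 2], ncol = 1)
  cfg1 <- forest_config(n_trees = 1, max_depth = 3, min_leaf_samples = 20,
                        seed = 5)
  f1 <- train_forest(list(features = XL, targets = XH), cfg1)
  expect_length(f1$trees, 1)
  x <- c(0.3, -0.4)
  X <- matrix(x, 1)
  single <- rfctsr:::predict_tree(f1$trees[[1]], X, basis_expand(X),
                                  matrix(0, 1, 1))
  expect_equal(predict_patch(f1, x), as.vector(single), tolerance = 1e-12)

  cfg <- forest_config(n_trees = 3, max_depth = 3, min_leaf_samples = 20,
                       seed = 9)
  fa <- train_forest(list(features = XL, targets = XH), cfg)
  fb <- train_forest(list(features = XL, targets = XH), cfg)
  expect_identical(fa, fb)

  # ensemble mean: hand-built two-leaf forest predicting (a + b) / 2
  mk_leaf_tree <- function(w) list(type = "leaf", W = w, n_train = 10,
                                   depth = 0L)
  a <- matrix(c(1, 0, 0), 1, 3); b <- matrix(c(3, 0, 0), 1, 3)
  hand <- structure(list(trees = list(mk_leaf_tree(a), mk_leaf_tree(b)),
                         basis = basis_spec(), config = cfg,
                         min_leaf_samples = 10L, d_features = 2L,
                         d_targets = 1L),
                    class = "regression_forest")
  expect_equal(predict_patch(hand, c(5, 5)), 2)

  expect_error(predict_patch(fa, c(1, 2, 3)), "dimension")
})

test_that("planted linear mapping is recovered at the expected error-decay rate", {
  # x_H = A Psi(x_L) + noise; Frobenius RMSE of a depth-0 forest should halve
  # (within 30%) when N quadruples
  d <- 4; q <- 3
  rmse_at <- function(N, reps = 6) {
    mean(vapply(seq_len(reps), function(r) {
      set.seed(1000 + r)
      A <- matrix(rnorm(q * (d + 1)), q, d + 1)
      XL <- matrix(rnorm(N * d), N, d)
      XH <- basis_expand(XL) %*% t(A) + 0.5 * matrix(rnorm(N * q), N, q)
      f <- train_forest(list(features = XL, targets = XH),
                        forest_config(n_trees = 1, max_depth = 0,
                                      ridge = 1e-8, min_leaf_samples = 10,
                                      seed = r))
      sqrt(mean((f$trees[[1]]$W - A)^2))
    }, numeric(1)))
  }
  r1 <- rmse_at(250)
  r2 <- rmse_at(1000)
  expect_equal(r2 / r1, 0.5, tolerance = 0.3)
})
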