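# Regression random forest with closed-form ridge leaf models.
#
# Each tree recursively splits the LD feature space with thresholded split
# functions delta(x, Theta) in {0, 1} (0 iff r_Theta(x) < 0; equality routes
# to the "1" branch). Candidate splits are scored by the weighted child
# impurity Q = |X_Left| E_Left + |X_Right| E_Right where the impurity
#   E(X_L, X_H) = mean( ||x_H - m(x_L)||^2 + k ||x_L - mean(x_L)||^2 )
# combines the label-space residual with k times the data-space scatter.
# Leaves store the ridge solution
#   W^T = (Psi(X_L)^T Psi(X_L) + eta I)^{-1} Psi(X_L)^T X_H
# over basis-expanded features, and the forest prediction is the arithmetic
# mean of the T leaf-model outputs.

#' Basis expansion specification
#'
#' @param kind `"linear"` (`[1, x]`) or `"polynomial"`
#'   (`[1, x, x^2, ..., x^gamma]`, elementwise powers).
#' @param gamma Highest basis index (default 1; `kind = "linear"` implies
#'   `gamma = 1`). `gamma = 0` with a constant gives the intercept-only basis.
#' @param includes_constant Include the constant basis function (default TRUE).
#' @return A `basis_spec` list.
#' @export
basis_spec <- function(kind = c("linear", "polynomial"), gamma = 1,
                       includes_constant = TRUE) {
  kind <- match.arg(kind)
  if (gamma < 0) stop_input("gamma must be a nonnegative integer")
  if (kind == "linear" && gamma > 1) {
    stop_input("kind = 'linear' implies gamma <= 1; use kind = 'polynomial'")
  }
  if (gamma == 0 && !includes_constant) {
    stop_input("gamma = 0 without a constant leaves an empty basis")
  }
  structure(list(kind = kind, gamma = as.integer(gamma),
                 includes_constant = isTRUE(includes_constant)),
            class = "basis_spec")
}

#' Expand features through the basis
#'
#' @param x A numeric vector (one sample) or an n x D matrix (rows = samples).
#' @param basis A [basis_spec()].
#' @return The expanded vector, or n x P matrix.
#' @export
basis_expand <- function(x, basis = basis_spec()) {
  vec <- !is.matrix(x)
  X <- if (vec) matrix(x, nrow = 1) else x
  blocks <- if (basis$includes_constant) list(matrix(1, nrow(X), 1)) else list()
  if (basis$gamma >= 1) {
    blocks <- c(blocks, lapply(seq_len(basis$gamma), function(p) X^p))
  }
  out <- do.call(cbind, blocks)
  if (vec) as.vector(out) else out
}

basis_dim <- function(d, basis) {
  basis$gamma * d + as.integer(basis$includes_constant)
}

#' Forest training configuration
#'
#' Defaults follow the method's standard operating point: `n_trees = 10`,
#' `max_depth = 15`, ridge `eta = 0.01`, data-space split regularizer
#' `k = 1`.
#'
#' @param n_trees Number of trees T.
#' @param max_depth Maximum tree depth (root has depth 0).
#' @param ridge Ridge regularizer eta for the leaf models.
#' @param split_reg Data-space regularizer k in the impurity.
#' @param n_candidate_splits Random split candidates scored per node.
#' @param min_leaf_samples Minimum samples per leaf; default
#'   `max(32, basis dimension + 1)`, resolved at training time.
#' @param bootstrap_fraction Per-tree bootstrap size as a fraction of N,
#'   sampled with replacement.
#' @param split_form `"single"` (threshold one feature) or `"pair"`
#'   (threshold the difference of two features).
#' @param exact_split_purity If TRUE, score candidates with a full ridge
#'   refit per child (slow, fidelity checks); default uses the node-mean
#'   predictor for the label term and refits only accepted children.
#' @param seed Integer seed; per-tree and per-node streams are derived.
#' @return A `forest_config` list.
#' @export
forest_config <- function(n_trees = 10, max_depth = 15, ridge = 0.01,
                          split_reg = 1, n_candidate_splits = 40,
                          min_leaf_samples = NULL, bootstrap_fraction = 1,
                          split_form = c("single", "pair"),
                          exact_split_purity = FALSE, seed = 1) {
  split_form <- match.arg(split_form)
  if (n_trees < 1) stop_input("n_trees must be positive")
  if (max_depth < 0) stop_input("max_depth must be nonnegative")
  if (ridge < 0) stop_input("ridge must be nonnegative")
  if (split_reg < 0) stop_input("split_reg (k) must be nonnegative")
  if (n_candidate_splits < 1) stop_input("n_candidate_splits must be positive")
  if (bootstrap_fraction <= 0 || bootstrap_fraction > 1) {
    stop_input("bootstrap_fraction must be in (0, 1]")
  }
  structure(list(n_trees = as.integer(n_trees),
                 max_depth = as.integer(max_depth), ridge = ridge,
                 split_reg = split_reg,
                 n_candidate_splits = as.integer(n_candidate_splits),
                 min_leaf_samples = min_leaf_samples,
                 bootstrap_fraction = bootstrap_fraction,
                 split_form = split_form,
                 exact_split_purity = isTRUE(exact_split_purity),
                 seed = as.integer(seed)),
            class = "forest_config")
}

resolve_min_leaf <- function(cfg, d_feat, basis) {
  if (!is.null(cfg$min_leaf_samples)) return(as.integer(cfg$min_leaf_samples))
  max(32L, basis_dim(d_feat, basis) + 1L)
}

#' Fit the closed-form ridge leaf model
#'
#' Solves `argmin ||X_H - W Psi(X_L)||^2 + eta ||W||^2` via the normal
#' equations `W^T = (Psi^T Psi + eta I)^{-1} Psi^T X_H`.
#'
#' @param X_L n x D_L sample matrix (rows = samples).
#' @param X_H n x D_H target matrix.
#' @param basis A [basis_spec()].
#' @param ridge Ridge parameter eta (`> 0`, or 0 only if the Gram matrix is
#'   nonsingular).
#' @return A `leaf_model`: list with `W` (D_H x P) and `n_train`.
#' @export
fit_leaf_model <- function(X_L, X_H, basis = basis_spec(), ridge = 0.01) {
  X_L <- as_sample_matrix(X_L); X_H <- as_sample_matrix(X_H)
  if (nrow(X_L) < 1) stop_input("leaf model needs at least one sample")
  Psi <- basis_expand(X_L, basis)
  A <- crossprod(Psi)
  diag(A) <- diag(A) + ridge
  Wt <- tryCatch(solve(A, crossprod(Psi, X_H)), error = function(e) {
    stop_input("singular leaf system (Gram matrix not invertible with ",
               "ridge = ", ridge, "); increase the ridge parameter")
  })
  structure(list(W = t(Wt), n_train = nrow(X_L)), class = "leaf_model")
}

as_sample_matrix <- function(x) {
  if (is.matrix(x)) x else matrix(x, ncol = 1)
}

predict_leaf <- function(leaf, Psi) Psi %*% t(leaf$W)   # n x D_H

#' Evaluate the binary split function
#'
#' `r(x) = x[feature_index] - threshold` (single form) or
#' `x[feature_index] - x[second_feature_index] - threshold` (pair form);
#' returns 0 iff `r < 0`, otherwise 1 (equality routes to 1).
#'
#' @param x_L Feature vector, or n x D matrix for vectorized evaluation.
#' @param theta List with `feature_index` (0-based), optional
#'   `second_feature_index`, `threshold`.
#' @return Integer 0/1 (or vector).
#' @export
split_response <- function(x_L, theta) {
  X <- if (is.matrix(x_L)) x_L else matrix(x_L, nrow = 1)
  i <- theta$feature_index + 1L
  if (i < 1L || i > ncol(X)) stop_input("feature_index out of range")
  r <- X[, i]
  if (!is.null(theta$second_feature_index) &&
      !is.na(theta$second_feature_index)) {
    j <- theta$second_feature_index + 1L
    if (j < 1L || j > ncol(X)) stop_input("second_feature_index out of range")
    r <- r - X[, j]
  }
  out <- as.integer(r - theta$threshold >= 0)
  if (is.matrix(x_L)) out else out[1]
}

# Impurity with an explicit predictor choice. predictor = "mean" uses the
# constant node-mean target predictor (the cheap split-search variant);
# "ridge" fits the node's ridge leaf model as in the impurity definition.
node_purity_impl <- function(X_L, X_H, k, basis, ridge, predictor) {
  n <- nrow(X_L)
  if (n < 1) stop_input("purity of an empty node is undefined")
  if (predictor == "ridge") {
    leaf <- fit_leaf_model(X_L, X_H, basis, ridge)
    resid <- X_H - predict_leaf(leaf, basis_expand(X_L, basis))
  } else {
    resid <- sweep(X_H, 2, colMeans(X_H))
  }
  scatter <- sweep(X_L, 2, colMeans(X_L))
  mean(rowSums(resid^2)) + k * mean(rowSums(scatter^2))
}

#' Node impurity: prediction residual plus data-space scatter
#'
#' `E(X_L, X_H) = mean(||x_H - m(x_L)||^2 + k ||x_L - mean(x_L)||^2)` where
#' `m` is the node's fitted ridge leaf model (`predictor = "ridge"`) or the
#' node-mean target predictor (`predictor = "mean"`, the cheap variant used
#' inside split search).
#'
#' @param X_L,X_H Sample and target matrices (rows = samples).
#' @param k Data-space regularizer.
#' @param basis,ridge Leaf-model settings (used when `predictor = "ridge"`).
#' @param predictor `"ridge"` or `"mean"`.
#' @return Nonnegative scalar.
#' @export
node_purity <- function(X_L, X_H, k = 1, basis = basis_spec(), ridge = 0.01,
                        predictor = c("ridge", "mean")) {
  predictor <- match.arg(predictor)
  node_purity_impl(as_sample_matrix(X_L), as_sample_matrix(X_H),
                   k, basis, ridge, predictor)
}

#' Score one candidate split
#'
#' `Q = |X_Left| E_Left + |X_Right| E_Right`; lower is better. A candidate
#' sending fewer than `min_leaf` samples to either side is inadmissible and
#' returns `Inf` (a sentinel, not an error).
#'
#' @param theta Split parameters (see [split_response()]).
#' @param X_L,X_H Node sample and target matrices.
#' @param k Data-space regularizer.
#' @param basis,ridge Leaf-model settings.
#' @param min_leaf Admissibility floor per child (default 1).
#' @param predictor `"mean"` (default, matches tree growth) or `"ridge"`.
#' @return Nonnegative scalar, or `Inf` for an inadmissible candidate.
#' @export
split_quality <- function(theta, X_L, X_H, k = 1, basis = basis_spec(),
                          ridge = 0.01, min_leaf = 1,
                          predictor = c("mean", "ridge")) {
  predictor <- match.arg(predictor)
  X_L <- as_sample_matrix(X_L); X_H <- as_sample_matrix(X_H)
  d <- split_response(X_L, theta)
  nl <- sum(d == 0); nr <- sum(d == 1)
  if (nl < min_leaf || nr < min_leaf) return(Inf)
  ql <- nl * node_purity_impl(X_L[d == 0, , drop = FALSE],
                              X_H[d == 0, , drop = FALSE],
                              k, basis, ridge, predictor)
  qr <- nr * node_purity_impl(X_L[d == 1, , drop = FALSE],
                              X_H[d == 1, , drop = FALSE],
                              k, basis, ridge, predictor)
  ql + qr
}

# Draw candidate split parameters for one node: random feature (or feature
# pair) and a threshold uniform between the 5th and 95th percentile of the
# candidate's response over the node samples. Returns a data.frame.
draw_split_candidates <- function(X_L, n_candidates, split_form, seed) {
  d <- ncol(X_L)
  withr::with_seed(seed, {
    fi <- sample.int(d, n_candidates, replace = TRUE)
    fj <- if (split_form == "pair") {
      vapply(fi, function(i) sample.int(d, 1), integer(1))
    } else rep(NA_integer_, n_candidates)
    resp <- X_L[, fi, drop = FALSE]
    if (split_form == "pair") resp <- resp - X_L[, fj, drop = FALSE]
    qs <- apply(resp, 2, stats::quantile, probs = c(0.05, 0.95), names = FALSE)
    thr <- stats::runif(n_candidates, qs[1, ], qs[2, ])
    data.frame(feature_index = fi - 1L, second_feature_index = fj - 1L,
               threshold = thr)
  })
}

# Vectorized Q over all candidates using sufficient statistics:
# n_c * E_c = (SqH_c - n_c ||muH_c||^2) + k (SqL_c - n_c ||muL_c||^2),
# with child column sums obtained by one crossprod over the mask matrix.
score_candidates <- function(X_L, X_H, cand, k, min_leaf) {
  n <- nrow(X_L)
  resp <- X_L[, cand$feature_index + 1L, drop = FALSE]
  pair <- !is.na(cand$second_feature_index)
  if (any(pair)) {
    resp[, pair] <- resp[, pair] -
      X_L[, cand$second_feature_index[pair] + 1L, drop = FALSE]
  }
  left <- sweep(resp, 2, cand$threshold) < 0      # n x n_cand logical
  nl <- colSums(left); nr <- n - nl
  sqL <- rowSums(X_L^2); sqH <- rowSums(X_H^2)
  totL <- colSums(X_L); totH <- colSums(X_H)
  M <- cbind(X_L, X_H, sqL, sqH)
  SL <- crossprod(left, M)                        # n_cand x (D_L + D_H + 2)
  dl <- ncol(X_L); dh <- ncol(X_H)
  sumL_l <- SL[, seq_len(dl), drop = FALSE]
  sumH_l <- SL[, dl + seq_len(dh), drop = FALSE]
  sqL_l <- SL[, dl + dh + 1]; sqH_l <- SL[, dl + dh + 2]
  sumL_r <- -sweep(sumL_l, 2, totL, "-")          # totL - sumL_l
  sumH_r <- -sweep(sumH_l, 2, totH, "-")
  sqL_r <- sum(sqL) - sqL_l; sqH_r <- sum(sqH) - sqH_l
  qleft <- (sqH_l - rowSums(sumH_l^2) / pmax(nl, 1)) +
    k * (sqL_l - rowSums(sumL_l^2) / pmax(nl, 1))
  qright <- (sqH_r - rowSums(sumH_r^2) / pmax(nr, 1)) +
    k * (sqL_r - rowSums(sumL_r^2) / pmax(nr, 1))
  Q <- qleft + qright
  Q[nl < min_leaf | nr < min_leaf] <- Inf
  list(Q = Q, left = left)
}

grow_node <- function(X_L, X_H, depth, cfg, basis, min_leaf, seed,
                      record = FALSE) {
  n <- nrow(X_L)
  make_leaf <- function() {
    leaf <- fit_leaf_model(X_L, X_H, basis, cfg$ridge)
    list(type = "leaf", W = leaf$W, n_train = n, depth = depth)
  }
  if (depth >= cfg$max_depth || n < 2L * min_leaf) return(make_leaf())
  cand <- draw_split_candidates(X_L, cfg$n_candidate_splits, cfg$split_form,
                                seed)
  if (cfg$exact_split_purity) {
    Q <- vapply(seq_len(nrow(cand)), function(j) {
      theta <- list(feature_index = cand$feature_index[j],
                    second_feature_index = cand$second_feature_index[j],
                    threshold = cand$threshold[j])
      split_quality(theta, X_L, X_H, cfg$split_reg, basis, cfg$ridge,
                    min_leaf, predictor = "ridge")
    }, numeric(1))
    left_of <- function(j) {
      theta <- list(feature_index = cand$feature_index[j],
                    second_feature_index = cand$second_feature_index[j],
                    threshold = cand$threshold[j])
      split_response(X_L, theta) == 0L
    }
  } else {
    sc <- score_candidates(X_L, X_H, cand, cfg$split_reg, min_leaf)
    Q <- sc$Q
    left_of <- function(j) sc$left[, j]
  }
  best <- which.min(Q)                            # first minimum: lowest index
  if (!is.finite(Q[best])) return(make_leaf())
  parent_E <- node_purity_impl(X_L, X_H, cfg$split_reg, basis, cfg$ridge,
                               if (cfg$exact_split_purity) "ridge" else "mean")
  if (Q[best] / n >= parent_E * (1 - 1e-6)) return(make_leaf())
  lmask <- left_of(best)
  node <- list(
    type = "split",
    feature_index = cand$feature_index[best],
    second_feature_index = cand$second_feature_index[best],
    threshold = cand$threshold[best],
    depth = depth,
    left = grow_node(X_L[lmask, , drop = FALSE], X_H[lmask, , drop = FALSE],
                     depth + 1L, cfg, basis, min_leaf,
                     derive_seed(seed, 1L)),
    right = grow_node(X_L[!lmask, , drop = FALSE], X_H[!lmask, , drop = FALSE],
                      depth + 1L, cfg, basis, min_leaf,
                      derive_seed(seed, 2L))
  )
  if (record) {
    cand$quality <- Q
    attr(node, "root_candidates") <- cand
  }
  node
}

# Accept a patch_pairs object or list(features=, targets=).
training_matrices <- function(samples) {
  if (inherits(samples, "patch_pairs")) {
    list(X_L = samples$features, X_H = samples$targets)
  } else if (is.list(samples) && !is.null(samples$features)) {
    list(X_L = as_sample_matrix(samples$features),
         X_H = as_sample_matrix(samples$targets))
  } else stop_input("samples must be a patch_pairs object or a list with ",
                    "$features and $targets")
}

#' Grow one regression tree
#'
#' Greedy recursive growth: at each node, `n_candidate_splits` random split
#' candidates are drawn (random feature index or pair, threshold uniform
#' within the 5th-95th percentile of the response over node samples), scored
#' by [split_quality()], and the minimizer kept (ties broken by the lowest
#' candidate index). Growth stops at `max_depth`, when fewer than
#' `2 * min_leaf_samples` samples remain, or when no admissible candidate
#' improves on the unsplit impurity; a ridge leaf model is then fitted.
#' Deterministic given `rng_seed`.
#'
#' @param samples A `patch_pairs` object or `list(features=, targets=)`.
#' @param cfg A [forest_config()].
#' @param basis A [basis_spec()].
#' @param rng_seed Integer seed for this tree.
#' @param record_root If TRUE, attach the root candidate table (with scored
#'   qualities) as attribute `"root_candidates"`.
#' @return A nested `tree_node` list.
#' @export
grow_tree <- function(samples, cfg = forest_config(), basis = basis_spec(),
                      rng_seed = cfg$seed, record_root = FALSE) {
  tm <- training_matrices(samples)
  min_leaf <- resolve_min_leaf(cfg, ncol(tm$X_L), basis)
  if (nrow(tm$X_L) < min_leaf) {
    stop_input("too few samples at the root: ", nrow(tm$X_L), " < ", min_leaf)
  }
  grow_node(tm$X_L, tm$X_H, 0L, cfg, basis, min_leaf, rng_seed,
            record = record_root)
}

#' Train the regression forest
#'
#' Grows `n_trees` trees, each on an independent bootstrap draw (with
#' replacement, size `bootstrap_fraction * N`) with a per-tree seed derived
#' from `cfg$seed`.
#'
#' @inheritParams grow_tree
#' @return A `regression_forest`: list of tree roots plus `basis`, `config`
#'   and the resolved `min_leaf_samples`.
#' @export
train_forest <- function(samples, cfg = forest_config(),
                         basis = basis_spec()) {
  tm <- training_matrices(samples)
  n <- nrow(tm$X_L)
  min_leaf <- resolve_min_leaf(cfg, ncol(tm$X_L), basis)
  if (n < min_leaf) stop_input("too few samples: ", n, " < ", min_leaf)
  trees <- lapply(seq_len(cfg$n_trees), function(t) {
    seed_t <- derive_seed(cfg$seed, t)
    idx <- withr::with_seed(seed_t,
      sample.int(n, size = max(1L, round(cfg$bootstrap_fraction * n)),
                 replace = TRUE))
    grow_node(tm$X_L[idx, , drop = FALSE], tm$X_H[idx, , drop = FALSE],
              0L, cfg, basis, min_leaf, derive_seed(seed_t, 999L))
  })
  structure(list(trees = trees, basis = basis, config = cfg,
                 min_leaf_samples = min_leaf,
                 d_features = ncol(tm$X_L), d_targets = ncol(tm$X_H)),
            class = "regression_forest")
}

#' @export
print.regression_forest <- function(x, ...) {
  cat(sprintf("<regression_forest: %d trees, max depth %d, D_L=%d -> D_H=%d>\n",
              length(x$trees), x$config$max_depth, x$d_features, x$d_targets))
  invisible(x)
}

# Vectorized routing + leaf prediction for one tree over an n x D matrix.
predict_tree <- function(node, X, Psi, out) {
  stack <- list(list(node = node, idx = seq_len(nrow(X))))
  while (length(stack)) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    nd <- top$node; idx <- top$idx
    if (!length(idx)) next
    if (nd$type == "leaf") {
      out[idx, ] <- Psi[idx, , drop = FALSE] %*% t(nd$W)
    } else {
      r <- X[idx, nd$feature_index + 1L]
      if (!is.na(nd$second_feature_index)) {
        r <- r - X[idx, nd$second_feature_index + 1L]
      }
      go_left <- (r - nd$threshold) < 0
      stack[[length(stack) + 1L]] <- list(node = nd$left, idx = idx[go_left])
      stack[[length(stack) + 1L]] <- list(node = nd$right, idx = idx[!go_left])
    }
  }
  out
}

#' Forest prediction
#'
#' Routes each feature vector down every tree and returns the arithmetic
#' mean over trees of the leaf-model outputs `W Psi(x)`.
#'
#' @param forest A `regression_forest`.
#' @param x_L A feature vector or an n x D_L matrix.
#' @return Predicted target vector, or n x D_H matrix.
#' @export
predict_patch <- function(forest, x_L) {
  vec <- !is.matrix(x_L)
  X <- if (vec) matrix(x_L, nrow = 1) else x_L
  if (ncol(X) != forest$d_features) {
    stop_input("feature dimension ", ncol(X), " does not match training (",
               forest$d_features, ")")
  }
  Psi <- basis_expand(X, forest$basis)
  acc <- matrix(0, nrow(X), forest$d_targets)
  tmp <- matrix(0, nrow(X), forest$d_targets)
  for (tr in forest$trees) acc <- acc + predict_tree(tr, X, Psi, tmp)
  acc <- acc / length(forest$trees)
  if (vec) as.vector(acc) else acc
}

#' @rdname predict_patch
#' @param object A `regression_forest`.
#' @param newdata Feature matrix.
#' @param ... Unused.
#' @export
predict.regression_forest <- function(object, newdata, ...) {
  predict_patch(object, newdata)
}

# Structural walk helpers used by tests and serialization.
walk_leaves <- function(node, fn) {
  if (node$type == "leaf") fn(node)
  else c(walk_leaves(node$left, fn), walk_leaves(node$right, fn))
}
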