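# Sparse representation and coupled dictionary learning.
#
# Signals are represented as sparse combinations of dictionary atoms,
#   min_a ||x - D a||_2^2 + lambda ||a||_1,
# solved by ISTA (proximal gradient; the objective is nonincreasing per
# iteration). Coupled learning trains an LD dictionary D_L and an HD
# dictionary D_H sharing one sparse code matrix E by alternating sparse
# coding and a MOD-style least-squares dictionary update in the jointly
# weighted signal space
#   (1/D_L)||X_L - D_L E||^2 + (1/D_H)||X_H - D_H E||^2 + lambda ||E||_1.
# Throughout this file samples are stored as COLUMNS (math convention).

#' Construct a dictionary object
#'
#' @param atoms Signal-dimension x B numeric matrix; columns are atoms.
#' @param normalized Logical: are columns unit-norm?
#' @return A `dictionary`.
#' @export
dictionary <- function(atoms, normalized = FALSE) {
  if (!is.matrix(atoms) || !is.numeric(atoms)) {
    stop_input("atoms must be a numeric matrix")
  }
  structure(list(atoms = atoms, normalized = isTRUE(normalized)),
            class = "dictionary")
}

#' @export
print.dictionary <- function(x, ...) {
  cat(sprintf("<dictionary: %d-dim signals, %d atoms%s>\n",
              nrow(x$atoms), ncol(x$atoms),
              if (x$normalized) ", unit-norm" else ""))
  invisible(x)
}

#' Rescale dictionary columns to unit Euclidean norm
#' @param D A `dictionary`.
#' @return A normalized `dictionary`.
#' @export
normalize_dictionary <- function(D) {
  nrm <- sqrt(colSums(D$atoms^2))
  nrm[nrm < 1e-12] <- 1
  dictionary(sweep(D$atoms, 2, nrm, "/"), normalized = TRUE)
}

# Shared ISTA core. X: d x n signal columns; M: d x B effective dictionary
# (possibly H %*% D). Minimizes ||X - M A||_F^2 + lambda * sum|A| per column.
# Step 1/(2 L) with L = sigma_max(M)^2 makes the objective nonincreasing.
ista_core <- function(X, M, lambda, max_iter, tol, A0 = NULL) {
  L <- max(svd(M, nu = 0, nv = 0)$d)^2
  if (L == 0) stop_input("dictionary is identically zero")
  step <- 1 / (2 * L)
  A <- if (is.null(A0)) matrix(0, ncol(M), ncol(X)) else A0
  G <- crossprod(M, X)                            # M^T X, fixed
  MtM <- crossprod(M)
  obj <- function(A) {
    R <- X - M %*% A
    sum(R^2) + lambda * sum(abs(A))
  }
  trace <- obj(A)
  for (it in seq_len(max_iter)) {
    grad <- MtM %*% A - G                         # (1/2) d/dA of the LS term
    Z <- A - 2 * step * grad
    thr <- step * lambda
    A_new <- sign(Z) * pmax(abs(Z) - thr, 0)
    f_new <- obj(A_new)
    if (f_new > trace[length(trace)] + 1e-10) break   # safeguard; ISTA step
    A <- A_new                                        # should never increase
    trace <- c(trace, f_new)
    if (length(trace) >= 2) {
      prev <- trace[length(trace) - 1]
      if (prev - f_new <= tol * max(1, prev)) break
    }
  }
  list(A = A, objective = trace)
}

sparse_code_result <- function(alpha, lambda, objective) {
  alpha_mat <- as_sample_matrix(alpha)
  structure(list(alpha = alpha, lambda = lambda,
                 nnz = sum(abs(alpha_mat) > 1e-12),
                 objective = objective,
                 iterations = length(objective) - 1L),
            class = "sparse_code")
}

#' @export
print.sparse_code <- function(x, ...) {
  cat(sprintf("<sparse_code: %d nonzeros, lambda %g, %d iterations, F=%.6g>\n",
              x$nnz, x$lambda, x$iterations,
              x$objective[length(x$objective)]))
  invisible(x)
}

#' Sparse-code a signal against a dictionary
#'
#' Minimizes `||x - D alpha||^2 + lambda ||alpha||_1` by ISTA; the recorded
#' objective trace is nonincreasing. With an orthonormal `D` and one step
#' this reduces to soft-thresholding `D^T x` at `lambda / 2`.
#'
#' @param x Signal vector, or d x n matrix of column signals.
#' @param D A normalized `dictionary`.
#' @param lambda Sparsity weight (`>= 0`).
#' @param max_iter,tol Iteration budget and relative-decrease stop.
#' @param warm_start Optional initial coefficient matrix.
#' @return A `sparse_code`: `alpha` (vector or B x n matrix), `lambda`,
#'   `nnz`, `objective` trace, `iterations`.
#' @export
sparse_code <- function(x, D, lambda = 0.1, max_iter = 200, tol = 1e-10,
                        warm_start = NULL) {
  backproject(x, D, degradation_operator("identity"), lambda,
              max_iter = max_iter, tol = tol, warm_start = warm_start)
}

#' Reconstruct a signal from its sparse code
#' @param D A `dictionary`.
#' @param alpha A `sparse_code` or a coefficient vector/matrix.
#' @return `D alpha` (vector or matrix).
#' @export
reconstruct_from_code <- function(D, alpha) {
  a <- if (inherits(alpha, "sparse_code")) alpha$alpha else alpha
  out <- D$atoms %*% as_sample_matrix(a)
  if (is.matrix(a)) out else as.vector(out)
}

#' Degradation operator relating HD to observed signals
#'
#' @param kind `"identity"` or `"blur_downsample"`.
#' @param blur_kernel Small odd-sided 2-D kernel (blur_downsample only).
#' @param factor Integer down-sampling factor.
#' @return A `degradation_operator`.
#' @export
degradation_operator <- function(kind = c("identity", "blur_downsample"),
                                 blur_kernel = matrix(c(1, 2, 1, 2, 4, 2,
                                                        1, 2, 1) / 16, 3, 3),
                                 factor = 2L) {
  kind <- match.arg(kind)
  if (factor < 1) stop_input("factor must be a positive integer")
  structure(list(kind = kind, blur_kernel = blur_kernel,
                 factor = as.integer(factor)),
            class = "degradation_operator")
}

# Dense matrix form of H for signals that are p x p patches flattened
# column-major. Blur uses clamped boundaries; down-sampling keeps every
# `factor`-th row/col starting at 1.
degradation_matrix <- function(op, signal_dim) {
  if (op$kind == "identity") return(diag(signal_dim))
  p <- as.integer(sqrt(signal_dim))
  if (p * p != signal_dim) stop_input("blur_downsample expects square patches")
  ker <- op$blur_kernel
  kr <- (nrow(ker) - 1L) %/% 2L; kc <- (ncol(ker) - 1L) %/% 2L
  clamp <- function(v) pmin(pmax(v, 1L), p)
  Bm <- matrix(0, signal_dim, signal_dim)
  for (j in seq_len(p)) for (i in seq_len(p)) {
    r <- (j - 1L) * p + i
    for (dj in seq_len(ncol(ker))) for (di in seq_len(nrow(ker))) {
      ii <- clamp(i + di - kr - 1L); jj <- clamp(j + dj - kc - 1L)
      cidx <- (jj - 1L) * p + ii
      Bm[r, cidx] <- Bm[r, cidx] + ker[di, dj]
    }
  }
  keep_ij <- seq(1L, p, by = op$factor)
  keep <- as.vector(outer(keep_ij, (keep_ij - 1L) * p, "+"))
  Bm[keep, , drop = FALSE]
}

#' Sparse coding through a degradation operator
#'
#' Minimizes `||y - H D alpha||^2 + lambda ||alpha||_1` with the same
#' proximal scheme as [sparse_code()]; with `H = identity` the two are the
#' same computation.
#'
#' @param y Observed vector (or matrix of column signals).
#' @param D A normalized `dictionary`.
#' @param H A [degradation_operator()].
#' @param lambda Sparsity weight.
#' @param max_iter,tol,warm_start As in [sparse_code()].
#' @return A `sparse_code`.
#' @export
backproject <- function(y, D, H = degradation_operator("identity"),
                        lambda = 0.1, max_iter = 200, tol = 1e-10,
                        warm_start = NULL) {
  stopifnot(inherits(D, "dictionary"))
  if (!D$normalized) stop_input("dictionary must be column-normalized ",
                                "(see normalize_dictionary)")
  Y <- as_sample_matrix(y)
  if (any(!is.finite(Y))) stop_input("non-finite values in the input signal")
  M <- if (H$kind == "identity") D$atoms
       else degradation_matrix(H, nrow(D$atoms)) %*% D$atoms
  if (nrow(M) != nrow(Y)) {
    stop_input("signal dimension ", nrow(Y), " does not match H(D x) = ",
               nrow(M))
  }
  fit <- ista_core(Y, M, lambda, max_iter, tol, A0 = warm_start)
  alpha <- if (is.matrix(y)) fit$A else as.vector(fit$A)
  sparse_code_result(alpha, lambda, fit$objective)
}

# Eq-5 style objective for the coupled problem in the weighted joint space.
coupled_objective <- function(Xj, Dj, E, lambda) {
  sum((Xj - Dj %*% E)^2) + lambda * sum(abs(E))
}

#' Learn coupled LD/HD dictionaries with a shared sparse code
#'
#' Alternates (a) ISTA sparse coding of the jointly weighted signals
#' `rbind(X_L / sqrt(D_L), X_H / sqrt(D_H))` against the joint dictionary,
#' (b) a MOD least-squares dictionary update, and (c) column
#' renormalization with the code rows rescaled to preserve the product; a
#' monotonicity guard skips the renormalization in any alternation where it
#' would increase the objective, so the recorded objective trace is
#' nonincreasing. Atoms are initialized from a seeded random subset of
#' training columns (with replacement, and a warning, if `N < B`).
#'
#' @param X_L,X_H Column-sample matrices (`D_L x N` and `D_H x N`, same N).
#' @param B Number of atoms (`>= 2`).
#' @param lambda Sparsity weight on the shared code.
#' @param n_iter Alternations; `0` returns the initialization unchanged
#'   (with a zero code matrix).
#' @param seed Integer seed for the initialization.
#' @param coding_iter ISTA iterations per alternation.
#' @return List with `D_L`, `D_H` (dictionaries in their own scales, i.e.
#'   `X_L ~ D_L E`), `E` (B x N code matrix), `objective` (per-alternation
#'   trace of the joint objective) and `joint` (the unit-norm joint
#'   dictionary).
#' @export
learn_coupled_dicts <- function(X_L, X_H, B = 256, lambda = 0.1, n_iter = 15,
                                seed = 1, coding_iter = 25) {
  if (B < 2) stop_input("B must be >= 2")
  X_L <- as_sample_matrix(X_L); X_H <- as_sample_matrix(X_H)
  if (ncol(X_L) != ncol(X_H)) stop_input("X_L and X_H must be column-paired")
  dl <- nrow(X_L); dh <- nrow(X_H); n <- ncol(X_L)
  Xj <- rbind(X_L / sqrt(dl), X_H / sqrt(dh))
  init_idx <- withr::with_seed(seed, {
    if (n < B) {
      warning("fewer samples than atoms; initializing with replacement")
      sample.int(n, B, replace = TRUE)
    } else sample.int(n, B)
  })
  Dj <- Xj[, init_idx, drop = FALSE]
  nrm <- sqrt(colSums(Dj^2)); nrm[nrm < 1e-12] <- 1
  Dj <- sweep(Dj, 2, nrm, "/")
  E <- matrix(0, B, n)
  trace <- coupled_objective(Xj, Dj, E, lambda)
  if (n_iter >= 1) {
    for (it in seq_len(n_iter)) {
      fit <- ista_core(Xj, Dj, lambda, coding_iter, tol = 1e-12, A0 = E)
      E <- fit$A
      # MOD: D <- X E^T (E E^T + eps I)^{-1}
      EEt <- tcrossprod(E)
      diag(EEt) <- diag(EEt) + 1e-9
      D_new <- t(solve(EEt, tcrossprod(E, Xj)))
      obj_mod <- coupled_objective(Xj, D_new, E, lambda)
      s <- sqrt(colSums(D_new^2)); s[s < 1e-12] <- 1
      D_nrm <- sweep(D_new, 2, s, "/")
      E_nrm <- E * s
      if (coupled_objective(Xj, D_nrm, E_nrm, lambda) <= obj_mod + 1e-12) {
        Dj <- D_nrm; E <- E_nrm
      } else {
        Dj <- D_new                               # guard: keep descent exact
      }
      # dead-atom replacement: an atom whose code row is (numerically) zero
      # contributes nothing, so swapping it for the currently
      # worst-represented signal leaves the objective unchanged while giving
      # the next coding pass a useful direction
      usage <- rowSums(abs(E))
      dead <- which(usage < 1e-8)
      if (length(dead)) {
        res <- colSums((Xj - Dj %*% E)^2)
        worst <- order(res, decreasing = TRUE)[seq_along(dead)]
        for (m in seq_along(dead)) {
          v <- Xj[, worst[m]]
          nv <- sqrt(sum(v^2))
          if (nv > 1e-12) Dj[, dead[m]] <- v / nv
        }
      }
      trace <- c(trace, coupled_objective(Xj, Dj, E, lambda))
    }
  }
  list(D_L = dictionary(Dj[seq_len(dl), , drop = FALSE] * sqrt(dl)),
       D_H = dictionary(Dj[dl + seq_len(dh), , drop = FALSE] * sqrt(dh)),
       E = E, objective = trace,
       joint = dictionary(Dj, normalized = TRUE))
}
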