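# Orthogonal matching pursuit, one column: greedy atom selection + LS refit.
omp_column <- function(x, B, sparsity, tol = 1e-12) {
  K <- ncol(B)
  y <- numeric(K)
  r <- x
  support <- integer(0)
  for (t in seq_len(sparsity)) {
    corr <- abs(drop(crossprod(B, r)))
    corr[support] <- -Inf
    k <- which.max(corr)
    if (!is.finite(corr[k]) || corr[k] < tol) break
    support <- c(support, k)
    Bs <- B[, support, drop = FALSE]
    ys <- drop(qr.coef(qr(Bs), x))
    ys[is.na(ys)] <- 0
    r <- x - drop(Bs %*% ys)
  }
  if (length(support)) y[support] <- ys
  y
}

#' Sparse-code a feature matrix with orthogonal matching pursuit
#'
#' @param X d x n numeric matrix (columns = images) or [feature_matrix()].
#' @param B d x K dictionary with unit-norm columns.
#' @param sparsity Maximum nonzeros per coding column.
#' @return K x n coding matrix.
#' @export
omp_encode <- function(X, B, sparsity) {
  if (inherits(X, "feature_matrix")) X <- X$X
  apply(X, 2, omp_column, B = B, sparsity = sparsity)
}

normalize_columns <- function(B) {
  nrm <- sqrt(colSums(B^2))
  nrm[nrm == 0] <- 1
  sweep(B, 2, nrm, "/")
}

#' Initialize dictionary and codes with K-SVD
#'
#' Starts from seeded random unit-norm atoms, then alternates OMP sparse
#' coding with rank-one SVD atom updates. Atoms unused by any coding column
#' are replaced by the (normalized) training column with the largest current
#' residual. An iteration that increases the reconstruction error
#' `||X - BY||_F` is reverted and iteration stops, so the error trace is
#' non-increasing.
#'
#' @param X d x n matrix or [feature_matrix()].
#' @param K Number of atoms (the training protocol default is K = n).
#' @param sparsity Nonzeros per coding column for OMP.
#' @param iters K-SVD iterations; `iters = 0` returns the random unit-column
#'   dictionary plus one OMP coding pass.
#' @param seed RNG seed for the initial atoms.
#' @return A list with `B` (d x K, unit columns), `Y` (K x n), and
#'   `errors` (reconstruction error after init and each kept iteration).
#' @export
ksvd_init <- function(X, K, sparsity, iters = 10, seed = 1) {
  if (inherits(X, "feature_matrix")) X <- X$X
  assert_finite_matrix(X, "X")
  d <- nrow(X); n <- ncol(X)
  if (K > n) warning("K > n: dictionary larger than the training set")
  if (sparsity > min(d, K)) srdml_stop("sparsity must be <= min(d, K)")
  B <- withr::with_seed(seed, normalize_columns(matrix(rnorm(d * K), d, K)))
  Y <- omp_encode(X, B, sparsity)
  errors <- fnorm(X - B %*% Y)
  if (iters < 1) return(list(B = B, Y = Y, errors = errors))
  for (it in seq_len(iters)) {
    B_prev <- B; Y_prev <- Y
    for (k in seq_len(K)) {
      omega <- which(abs(Y[k, ]) > 0)
      if (length(omega) == 0) {
        res <- colSums((X - B %*% Y)^2)
        worst <- which.max(res)
        col <- X[, worst]
        if (sum(col^2) < 1e-24) {            # degenerate zero column
          col <- withr::with_seed(seed + k, rnorm(d))
        }
        B[, k] <- col / sqrt(sum(col^2))
        next
      }
      Ek <- X[, omega, drop = FALSE] - B %*% Y[, omega, drop = FALSE] +
        tcrossprod(B[, k], Y[k, omega])
      sv <- svd(Ek, nu = 1, nv = 1)
      u <- drop(sv$u); v <- drop(sv$v)
      s <- sign(u[which.max(abs(u))]); if (s == 0) s <- 1   # deterministic sign
      B[, k] <- s * u
      Y[k, omega] <- s * sv$d[1] * v
    }
    Y_new <- omp_encode(X, B, sparsity)
    err <- fnorm(X - B %*% Y_new)
    if (err > utils::tail(errors, 1) + 1e-12) {
      B <- B_prev; Y <- Y_prev
      break
    }
    Y <- Y_new
    errors <- c(errors, err)
  }
  list(B = B, Y = Y, errors = errors)
}

#' Closed-form dictionary update
#'
#' Minimizes `||X - BY||_F^2` by the unconstrained least-squares solution
#' `B0 = X t(Y) solve(Y t(Y))`, then restores the unit-column constraint by
#' normalizing each atom and rescaling the corresponding row of Y by the same
#' factor (an exact reparameterization: the product BY, hence the
#' reconstruction error, is unchanged by the normalization).
#'
#' @param X d x n matrix or [feature_matrix()].
#' @param Y Current K x n coding matrix.
#' @return A list with the unit-column dictionary `B` and the compensated
#'   coding matrix `Y`.
#' @export
update_dictionary <- function(X, Y) {
  if (inherits(X, "feature_matrix")) X <- X$X
  K <- nrow(Y)
  G <- tcrossprod(Y)
  ok <- TRUE
  B0 <- tryCatch(t(solve(G, tcrossprod(Y, X))), error = function(e) {ok <<- FALSE; NULL})
  if (!ok || !all(is.finite(B0)) || rcond(G) < 1e-14) {
    warning("Y t(Y) is (near-)singular; adding ridge")
    G <- G + diag(1e-8 * sum(diag(G)) / K + 1e-12, K)
    B0 <- t(solve(G, tcrossprod(Y, X)))
  }
  nrm <- sqrt(colSums(B0^2))
  zero <- nrm < 1e-12
  if (any(zero)) {
    # unused atoms: point at the strongest data column, leave their ~zero rows
    strongest <- which.max(colSums(X^2))
    B0[, zero] <- X[, strongest] / sqrt(sum(X[, strongest]^2))
    nrm[zero] <- 1
  }
  B <- sweep(B0, 2, nrm, "/")
  Y <- Y * nrm   # row i scaled by nrm[i] (recycling down columns)
  list(B = B, Y = Y)
}

# Per-sweep frozen weights g'(Lambda_ij) for all pairs.
pair_weights <- function(Y, M, pairs, tau, theta) {
  if (nrow(pairs) == 0) return(numeric(0))
  D <- Y[, pairs$i, drop = FALSE] - Y[, pairs$j, drop = FALSE]
  d2 <- colSums(D * (M %*% D))
  glogistic_deriv(1 - pairs$ell * (tau - d2), theta)
}

#' Closed-form update of one coding column
#'
#' Solves the stationary condition of the per-column objective (data fidelity,
#' atom-locality, ridge, and pairwise terms with the logistic weights frozen at
#' the current iterate):
#' `(B'B + gamma I + alpha L + beta * sum_j w_ij l_ij M) y_i =
#'  B'x_i + beta * M (sum_j w_ij l_ij y_j)`.
#' With `alpha = beta = 0` this is ridge regression on the dictionary.
#'
#' @param i Column index to update.
#' @param X d x n matrix or [feature_matrix()].
#' @param B Dictionary (d x K).
#' @param Y Current coding matrix (K x n); other columns are frozen.
#' @param M Metric matrix (K x K).
#' @param L Atom Laplacian (K x K matrix or [build_laplacian()] output).
#' @param pairs Pair-constraint tibble from [build_pairs()] (may be empty).
#' @param hp [srdml_hparams()] (uses alpha, beta, gamma, tau, theta).
#' @param weights Optional frozen logistic weights per pair row (computed from
#'   the current Y when NULL).
#' @return The updated column `y_i` (length K).
#' @export
update_coding_column <- function(i, X, B, Y, M, L, pairs, hp, weights = NULL) {
  if (inherits(X, "feature_matrix")) X <- X$X
  L <- laplacian_matrix(L)
  K <- ncol(B)
  if (is.null(weights)) weights <- pair_weights(Y, M, pairs, hp$tau, hp$theta)
  A <- crossprod(B) + diag(hp$gamma, K) + hp$alpha * L
  rhs <- drop(crossprod(B, X[, i]))
  if (hp$beta > 0 && nrow(pairs) > 0) {
    hit_i <- pairs$i == i
    hit_j <- pairs$j == i
    if (any(hit_i) || any(hit_j)) {
      other <- c(pairs$j[hit_i], pairs$i[hit_j])
      wl <- c(weights[hit_i] * pairs$ell[hit_i], weights[hit_j] * pairs$ell[hit_j])
      A <- A + hp$beta * sum(wl) * M
      rhs <- rhs + hp$beta * drop(M %*% (Y[, other, drop = FALSE] %*% wl))
    }
  }
  out <- tryCatch(solve(A, rhs), error = function(e) NULL)
  if (is.null(out) || !all(is.finite(out))) {
    warning("coding system (near-)singular for column ", i, "; adding ridge")
    out <- solve(A + diag(1e-8, K), rhs)
  }
  drop(out)
}

#' One Gauss-Seidel sweep of coding-coefficient updates
#'
#' Updates columns in ascending index order using freshly updated columns
#' within the sweep; logistic weights are frozen at the sweep's starting
#' iterate and re-evaluated between sweeps. Because the joint objective is
#' column-separable given the other columns, each closed-form column update is
#' safeguarded on its exact objective contribution: an update that would
#' increase it is damped toward the previous column (up to 6 halvings) and
#' reverted when damping does not help (the frozen-weight system can be
#' indefinite when dissimilar-pair repulsion dominates). A final sweep-level
#' check enforces the same guarantee on the full objective.
#'
#' @inheritParams update_coding_column
#' @return The updated K x n coding matrix; the joint objective (B, M, L
#'   fixed) does not increase.
#' @export
update_coding <- function(X, B, Y, M, L, pairs, hp) {
  if (inherits(X, "feature_matrix")) X <- X$X
  Lm <- laplacian_matrix(L)
  obj0 <- srdml_objective(X, B, Y, M, Lm, pairs, hp)$total
  weights <- pair_weights(Y, M, pairs, hp$tau, hp$theta)
  Y_new <- Y
  use_pairs <- hp$beta > 0 && nrow(pairs) > 0
  col_obj <- function(yi, i, hit_i, hit_j) {
    val <- sum((X[, i] - B %*% yi)^2) +
      hp$alpha * drop(crossprod(yi, Lm %*% yi)) + hp$gamma * sum(yi^2)
    if (use_pairs && (any(hit_i) || any(hit_j))) {
      other <- c(pairs$j[hit_i], pairs$i[hit_j])
      ell <- c(pairs$ell[hit_i], pairs$ell[hit_j])
      Dq <- Y_new[, other, drop = FALSE] - yi
      d2 <- colSums(Dq * (M %*% Dq))
      val <- val + hp$beta * sum(glogistic(1 - ell * (hp$tau - d2), hp$theta))
    }
    val
  }
  for (i in seq_len(ncol(Y))) {
    hit_i <- if (use_pairs) pairs$i == i else logical(0)
    hit_j <- if (use_pairs) pairs$j == i else logical(0)
    y_old <- Y_new[, i]
    f_old <- col_obj(y_old, i, hit_i, hit_j)
    y_try <- update_coding_column(i, X, B, Y_new, M, Lm, pairs, hp,
                                  weights = weights)
    tol_i <- 1e-12 * max(abs(f_old), 1)
    accepted <- FALSE
    for (h in 0:6) {
      if (col_obj(y_try, i, hit_i, hit_j) <= f_old + tol_i) {
        Y_new[, i] <- y_try
        accepted <- TRUE
        break
      }
      y_try <- (y_try + y_old) / 2
    }
    if (!accepted) Y_new[, i] <- y_old
  }
  tol <- 1e-9 * max(abs(obj0), 1)
  obj1 <- srdml_objective(X, B, Y_new, M, Lm, pairs, hp)$total
  if (obj1 <= obj0 + tol) return(Y_new)
  for (h in seq_len(6)) {
    Y_new <- (Y + Y_new) / 2
    obj1 <- srdml_objective(X, B, Y_new, M, Lm, pairs, hp)$total
    if (obj1 <= obj0 + tol) {
      message("coding sweep damped (", h, " halving(s)) to preserve descent")
      return(Y_new)
    }
  }
  message("coding sweep reverted: no descent found")
  Y
}

#' Ridge-code a query against a trained dictionary
#'
#' Queries carry no labels or pairwise constraints, so they are coded with the
#' gamma-regularized ridge solution `y = solve(B'B + gamma I, B'x)` — identical
#' to the training update with the locality and pairwise terms switched off.
#'
#' @param x Length-d feature vector, or d x q matrix of queries in columns.
#' @param B Trained dictionary (d x K).
#' @param gamma Ridge weight (use the training value).
#' @return Length-K code (or K x q matrix for matrix input).
#' @export
encode_query <- function(x, B, gamma) {
  x <- as.matrix(x)
  if (nrow(x) != nrow(B)) srdml_stop("query has ", nrow(x), " features; dictionary has ", nrow(B))
  A <- crossprod(B) + diag(gamma, ncol(B))
  out <- solve(A, crossprod(B, x))
  if (ncol(out) == 1) drop(out) else out
}
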