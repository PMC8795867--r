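#' Squared Mahalanobis distance between code vectors
#'
#' `d_M^2(u, v) = (u - v)' M (u - v)`; nonnegative whenever M is positive
#' semidefinite, and equal to squared Euclidean distance for M = I.
#'
#' @param u,v Numeric vectors of equal length K.
#' @param M K x K metric matrix.
#' @return Nonnegative scalar.
#' @examples
#' mahalanobis_sq(c(3, 4), c(0, 0), diag(2)) # 25
#' @export
mahalanobis_sq <- function(u, v, M) {
  if (length(u) != length(v) || length(u) != nrow(M)) {
    srdml_stop("shape mismatch: |u| = ", length(u), ", |v| = ", length(v),
               ", M is ", nrow(M), " x ", ncol(M))
  }
  w <- u - v
  drop(crossprod(w, M %*% w))
}

#' Generalized logistic (softplus) loss and its derivative
#'
#' `g(y) = log(1 + exp(theta * y)) / theta`, a smooth upper bound of the hinge
#' `max(0, y)` with sharpness `theta`; computed overflow-safely. The derivative
#' is the logistic `g'(y) = 1 / (1 + exp(-theta * y))`.
#'
#' @param y Numeric vector.
#' @param theta Sharpness, > 0 (default 1).
#' @return Numeric vector of the same length.
#' @export
glogistic <- function(y, theta = 1) {
  if (theta <= 0) srdml_stop("theta must be positive")
  z <- theta * y
  out <- ifelse(z > 30, y + exp(-pmin(z, 700)) / theta, log1p(exp(pmin(z, 30))) / theta)
  as.numeric(out)
}

#' @rdname glogistic
#' @export
glogistic_deriv <- function(y, theta = 1) {
  if (theta <= 0) srdml_stop("theta must be positive")
  stats::plogis(theta * y)
}

#' Build pairwise similarity constraints from class labels
#'
#' Enumerates unordered index pairs with `ell = +1` when the two labels agree
#' and `-1` otherwise. When `max_pairs` is finite and smaller than the number
#' of available pairs, a balanced sample (half similar, half dissimilar, capped
#' by availability, without replacement, seeded) is drawn.
#'
#' @param labels Integer-like class labels, length n >= 2.
#' @param max_pairs Maximum pairs to keep (default `Inf` = all pairs).
#' @param seed RNG seed for sampling.
#' @return Tibble with columns `i`, `j` (i < j) and `ell` (+1 / -1).
#' @export
build_pairs <- function(labels, max_pairs = Inf, seed = 1) {
  n <- length(labels)
  if (n < 2) srdml_stop("need at least two samples to form pairs")
  idx <- utils::combn(n, 2)
  ell <- ifelse(labels[idx[1, ]] == labels[idx[2, ]], 1L, -1L)
  if (all(ell == 1L)) warning("only one class present: no dissimilar pairs")
  pairs <- tibble::tibble(i = idx[1, ], j = idx[2, ], ell = ell)
  if (is.finite(max_pairs) && nrow(pairs) > max_pairs) {
    half <- floor(max_pairs / 2)
    sim <- which(pairs$ell == 1L)
    dis <- which(pairs$ell == -1L)
    keep <- withr::with_seed(seed, {
      c(
        sample(sim, min(half, length(sim))),
        sample(dis, min(max_pairs - min(half, length(sim)), length(dis)))
      )
    })
    pairs <- pairs[sort(keep), ]
  }
  pairs
}

# Squared metric distances for all pairs at once.
pair_distances <- function(Y, M, pairs) {
  if (nrow(pairs) == 0) return(numeric(0))
  D <- Y[, pairs$i, drop = FALSE] - Y[, pairs$j, drop = FALSE]
  colSums(D * (M %*% D))
}

#' Large-margin pairwise loss over coding coefficients
#'
#' Sum over constraint pairs of `g(1 - ell * (tau - d_M^2(y_i, y_j)))`:
#' similar pairs are pushed below distance `tau - 1`, dissimilar pairs above
#' `tau + 1`, with softplus slack.
#'
#' @param Y K x n coding matrix.
#' @param M K x K metric.
#' @param pairs [build_pairs()] tibble.
#' @param tau Threshold center.
#' @param theta Softplus sharpness.
#' @return Nonnegative scalar (0 for an empty pair set).
#' @export
pairwise_loss <- function(Y, M, pairs, tau, theta = 1) {
  if (nrow(pairs) == 0) return(0)
  d2 <- pair_distances(Y, M, pairs)
  sum(glogistic(1 - pairs$ell * (tau - d2), theta))
}

#' Gradient of the metric-block objective in M
#'
#' Returns the symmetric gradient
#' `beta * sum_pairs g'(Lambda_ij) ell_ij (y_i - y_j)(y_i - y_j)' +
#'  2 eta (M - I)`
#' of `beta * pairwise_loss + eta ||M - I||_F^2`, with
#' `Lambda_ij = 1 - ell_ij (tau - d_M^2(y_i, y_j))`.
#'
#' @inheritParams pairwise_loss
#' @param eta Weight of the `||M - I||^2` regularizer.
#' @param beta Weight of the pairwise term (default 1 gives the beta-free core).
#' @return K x K symmetric matrix.
#' @export
metric_gradient <- function(Y, M, pairs, tau, theta = 1, eta = 1, beta = 1) {
  K <- nrow(M)
  G <- 2 * eta * (M - diag(K))
  if (nrow(pairs) > 0) {
    D <- Y[, pairs$i, drop = FALSE] - Y[, pairs$j, drop = FALSE]
    d2 <- colSums(D * (M %*% D))
    w <- glogistic_deriv(1 - pairs$ell * (tau - d2), theta)
    coef <- w * pairs$ell
    G <- G + beta * tcrossprod(sweep(D, 2, coef, "*"), D)
  }
  (G + t(G)) / 2
}

#' Project a symmetric matrix onto the PSD cone with a rank bound
#'
#' Symmetrizes, eigendecomposes, clips negative eigenvalues to zero, and keeps
#' only the `m_rank` largest eigenvalues before reconstructing. A PSD input of
#' rank at most `m_rank` is a fixed point.
#'
#' @param M_raw Square numeric matrix.
#' @param m_rank Effective rank bound (default: full size).
#' @return Symmetric PSD matrix with at most `m_rank` positive eigenvalues.
#' @export
psd_project <- function(M_raw, m_rank = nrow(M_raw)) {
  S <- (M_raw + t(M_raw)) / 2
  e <- eigen(S, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  if (m_rank < length(vals)) vals[-seq_len(m_rank)] <- 0
  M <- e$vectors %*% (vals * t(e$vectors))
  (M + t(M)) / 2
}

#' One projected-gradient update of the metric matrix
#'
#' The input metric is first projected onto the feasible set (PSD with rank at
#' most `hp$m_rank`), then `hp$metric_steps` projected-gradient steps
#' `M <- psd_project(M - xi * grad)` are taken on the metric-block objective
#' `beta * pairwise_loss + eta ||M - I||^2`, halving the learning rate up to
#' 20 times until neither the block objective nor the pairwise term (the part
#' that enters the joint objective) increases relative to the feasible start.
#' If backtracking is exhausted the feasible projection of the previous M is
#' returned with a warning.
#'
#' @param Y K x n coding matrix.
#' @param M Current metric.
#' @param pairs [build_pairs()] tibble.
#' @param hp [srdml_hparams()] (uses beta, eta, xi, tau, theta, m_rank,
#'   metric_steps).
#' @return Updated K x K PSD metric with rank at most `hp$m_rank`.
#' @export
update_metric <- function(Y, M, pairs, hp) {
  if (hp$beta <= 0 || nrow(pairs) == 0) return(M)
  M <- psd_project(M, hp$m_rank)
  block_obj <- function(Mx) {
    hp$beta * pairwise_loss(Y, Mx, pairs, hp$tau, hp$theta) +
      hp$eta * sum((Mx - diag(nrow(Mx)))^2)
  }
  for (step in seq_len(hp$metric_steps)) {
    f0 <- block_obj(M)
    p0 <- pairwise_loss(Y, M, pairs, hp$tau, hp$theta)
    G <- metric_gradient(Y, M, pairs, hp$tau, hp$theta, hp$eta, hp$beta)
    xi <- hp$xi
    accepted <- FALSE
    for (bt in seq_len(20)) {
      M_try <- psd_project(M - xi * G, hp$m_rank)
      if (block_obj(M_try) <= f0 + 1e-12 * max(abs(f0), 1) &&
          pairwise_loss(Y, M_try, pairs, hp$tau, hp$theta) <=
            p0 + 1e-12 * max(abs(p0), 1)) {
        M <- M_try
        accepted <- TRUE
        break
      }
      xi <- xi / 2
    }
    if (!accepted) {
      warning("metric backtracking exhausted; keeping previous M")
      return(M)
    }
  }
  M
}

# Scale-adaptive default for the pairwise threshold center: 1 + median of the
# identity-metric squared distances over similar pairs (all pairs as fallback),
# so similar pairs start near their margin.
tau_default <- function(Y, pairs) {
  if (nrow(pairs) == 0) return(1)
  d2 <- pair_distances(Y, diag(nrow(Y)), pairs)
  sim <- pairs$ell == 1L
  base <- if (any(sim)) stats::median(d2[sim]) else stats::median(d2)
  1 + base
}
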