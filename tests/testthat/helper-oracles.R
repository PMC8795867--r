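# Independent numeric oracles used across the test files. These deliberately
# avoid the package's closed forms: central differences, brute-force sums,
# and generic numeric optimizers.

# Central-difference gradient of a scalar function of a vector.
num_grad <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(k) {
    xp <- x; xm <- x
    xp[k] <- xp[k] + h
    xm[k] <- xm[k] - h
    (f(xp) - f(xm)) / (2 * h)
  }, numeric(1))
}

# Numeric minimizer of ||X - B diag(s) Y||^2 over unit-column B with
# compensating row scales s (the same reparameterized problem the closed-form
# dictionary update solves), via BFGS on the unconstrained product A = B diag(s).
dict_oracle_value <- function(X, Y, n_starts = 3, seed = 1) {
  d <- nrow(X); K <- nrow(Y)
  f <- function(par) sum((X - matrix(par, d, K) %*% Y)^2)
  g <- function(par) as.numeric(-2 * (X - matrix(par, d, K) %*% Y) %*% t(Y))
  vals <- withr::with_seed(seed, {
    vapply(seq_len(n_starts), function(s) {
      par0 <- rnorm(d * K)
      stats::optim(par0, f, g, method = "BFGS",
                   control = list(maxit = 2000, reltol = 1e-15))$value
    }, numeric(1))
  })
  min(vals)
}

# Projected-gradient minimizer of ||X - BY||^2 over unit-column B with Y held
# fixed (the strictly constrained problem, no compensation).
dict_pgd_constrained <- function(X, Y, iters = 3000, seed = 1) {
  d <- nrow(X); K <- nrow(Y)
  normalize <- function(B) sweep(B, 2, pmax(sqrt(colSums(B^2)), 1e-12), "/")
  B <- withr::with_seed(seed, normalize(matrix(rnorm(d * K), d, K)))
  obj <- function(B) sum((X - B %*% Y)^2)
  f <- obj(B)
  step <- 0.1
  for (it in seq_len(iters)) {
    Gr <- -2 * (X - B %*% Y) %*% t(Y)
    B_try <- normalize(B - step * Gr)
    f_try <- obj(B_try)
    if (f_try <= f) {
      B <- B_try; f <- f_try; step <- step * 1.1
    } else {
      step <- step / 2
      if (step < 1e-14) break
    }
  }
  list(B = B, value = f)
}

# Average precision via the classic precision-curve formulation: mean of the
# precision values at the ranks of the relevant items.
ap_precision_curve <- function(relevance, n_relevant = sum(relevance)) {
  if (n_relevant < 1) return(NA_real_)
  pos <- which(relevance == 1)
  if (length(pos) == 0) return(0)
  prec_at <- cumsum(relevance)[pos] / pos
  sum(prec_at) / n_relevant
}

# Brute-force locality penalty: 0.5 * sum_ij P_ij ||row_i(Y) - row_j(Y)||^2.
locality_bruteforce <- function(Y, P) {
  K <- nrow(P)
  acc <- 0
  for (i in seq_len(K)) {
    for (j in seq_len(K)) {
      acc <- acc + P[i, j] * sum((Y[i, ] - Y[j, ])^2)
    }
  }
  acc / 2
}

fnorm_test <- function(x) sqrt(sum(x^2))

laplacian_of <- function(B, k_nn) build_laplacian(build_atom_graph(B, k_nn))

laplacian_matrix_test <- function(L) if (inherits(L, "atom_laplacian")) L$L else L

# Small random problem instances used by several files.
random_instance <- function(seed, d = 6, K = 4, n = 8, n_classes = 2) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(d * n), d, n)
    B <- matrix(rnorm(d * K), d, K)
    B <- sweep(B, 2, sqrt(colSums(B^2)), "/")
    Y <- matrix(rnorm(K * n, sd = 0.5), K, n)
    M <- crossprod(matrix(rnorm(K * K), K)) / K
    labels <- rep_len(seq_len(n_classes), n)
    list(X = X, B = B, Y = Y, M = M, labels = labels)
  })
}

# Shared fixture suite, built once per test run.
fixture_env <- new.env(parent = emptyenv())
get_fixtures <- function() {
  if (is.null(fixture_env$fx)) fixture_env$fx <- make_fixture_suite()
  fixture_env$fx
}

# Hyperparameters for fast small-instance training in tests.
tiny_hp <- function(...) {
  args <- utils::modifyList(
    list(K = 4, k_nn = 2, T_max = 6, ksvd_sparsity = 2, ksvd_iters = 3),
    list(...)
  )
  do.call(srdml_hparams, args)
}
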