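test_that("K-SVD drives the residual to zero on an orthonormal basis", {
  Q <- qr.Q(qr(withr::with_seed(31, matrix(rnorm(36), 6))))[, 1:4]
  out <- ksvd_init(Q, K = 4, sparsity = 1, iters = 40, seed = 2)
  expect_lt(fnorm_test(Q - out$B %*% out$Y), 1e-6)
  expect_lt(max(abs(sqrt(colSums(out$B^2)) - 1)), 1e-8)
  expect_true(all(colSums(out$Y != 0) <= 1))
})

test_that("K-SVD init honors its contracts", {
  inst <- random_instance(41)
  # iters = 0: seeded random unit atoms + one OMP pass
  out0 <- ksvd_init(inst$X, K = 4, sparsity = 2, iters = 0, seed = 5)
  B_expected <- withr::with_seed(5, {
    B <- matrix(rnorm(6 * 4), 6, 4)
    sweep(B, 2, sqrt(colSums(B^2)), "/")
  })
  expect_equal(out0$B, B_expected)
  expect_equal(out0$Y, omp_encode(inst$X, B_expected, 2))
  expect_true(all(colSums(out0$Y != 0) <= 2))

  # reconstruction error trace is non-increasing
  out <- ksvd_init(inst$X, K = 4, sparsity = 2, iters = 10, seed = 5)
  expect_true(all(diff(out$errors) <= 1e-12))

  expect_warning(ksvd_init(inst$X, K = 10, sparsity = 2, iters = 0, seed = 1), "K > n")
  expect_error(ksvd_init(inst$X, K = 4, sparsity = 5, iters = 0, seed = 1), "sparsity")
})

test_that("dictionary update matches closed forms in degenerate cases", {
  inst <- random_instance(51, d = 5, K = 1, n = 6)
  y <- matrix(inst$Y[1, ], 1)
  upd <- update_dictionary(inst$X, y)
  b_expected <- drop(inst$X %*% t(y)) / fnorm_test(inst$X %*% t(y))
  expect_equal(drop(upd$B), b_expected, tolerance = 1e-10)

  # Y = identity: column-normalized X, product preserved
  X <- random_instance(52, d = 5, K = 4, n = 4)$X
  upd <- update_dictionary(X, diag(4))
  expect_equal(upd$B, sweep(X, 2, sqrt(colSums(X^2)), "/"), tolerance = 1e-10)
  expect_equal(upd$B %*% upd$Y, X, tolerance = 1e-10)
})

test_that("dictionary update never worsens fidelity and reaches the oracle optimum", {
  for (seed in c(61, 62, 63)) {
    inst <- random_instance(seed, d = 5, K = 4, n = 6)
    before <- fnorm_test(inst$X - inst$B %*% inst$Y)
    upd <- update_dictionary(inst$X, inst$Y)
    after <- fnorm_test(inst$X - upd$B %*% upd$Y)
    expect_lte(after, before + 1e-12)
    expect_lt(max(abs(sqrt(colSums(upd$B^2)) - 1)), 1e-8)

    # matches the numeric minimizer of the reparameterized problem ...
    oracle <- dict_oracle_value(inst$X, inst$Y, seed = seed)
    expect_lt(abs(after^2 - oracle), 1e-6)
    # ... and cannot be beaten by the strictly constrained minimizer
    pgd <- dict_pgd_constrained(inst$X, inst$Y, seed = seed)
    expect_lte(after^2, pgd$value + 1e-6)
  }
})

test_that("coding updates reduce to ridge regression when alpha = beta = 0", {
  inst <- random_instance(71)
  hp <- srdml_hparams(alpha = 1e-12, beta = 1e-12, gamma = 0.3, tau = 1)
  hp$alpha <- 0; hp$beta <- 0
  L <- matrix(0, 4, 4)
  no_pairs <- tibble::tibble(i = integer(0), j = integer(0), ell = integer(0))
  Y1 <- update_coding(inst$X, inst$B, inst$Y, inst$M, L, no_pairs, hp)
  ridge <- solve(crossprod(inst$B) + diag(0.3, 4), crossprod(inst$B, inst$X))
  expect_equal(Y1, ridge, tolerance = 1e-10)

  yi <- update_coding_column(3, inst$X, inst$B, inst$Y, inst$M, L, no_pairs, hp)
  expect_equal(yi, ridge[, 3], tolerance = 1e-10)
})

test_that("a column untouched by pairs equals its beta = 0 update", {
  inst <- random_instance(72)
  hp <- srdml_hparams(alpha = 0.2, beta = 0.5, gamma = 0.1, tau = 1.5, k_nn = 2)
  L <- laplacian_of(inst$B, 2)
  pairs <- tibble::tibble(i = c(1L, 2L), j = c(2L, 4L), ell = c(1L, -1L))
  M <- psd_project(inst$M)
  y3_with <- update_coding_column(3, inst$X, inst$B, inst$Y, M, L, pairs, hp)
  hp0 <- hp; hp0$beta <- 0
  y3_without <- update_coding_column(3, inst$X, inst$B, inst$Y, M, L, pairs, hp0)
  expect_equal(y3_with, y3_without, tolerance = 1e-12)
})

test_that("column update zeroes the gradient of the frozen-weight objective", {
  inst <- random_instance(73, d = 6, K = 4, n = 8)
  hp <- srdml_hparams(alpha = 0.3, beta = 0.4, gamma = 0.2, tau = 1.2, theta = 1)
  L <- laplacian_of(inst$B, 2)
  M <- psd_project(inst$M)
  pairs <- build_pairs(inst$labels)
  i <- 2L
  w <- srdml:::pair_weights(inst$Y, M, pairs, hp$tau, hp$theta)
  yi <- update_coding_column(i, inst$X, inst$B, inst$Y, M, L, pairs, hp, weights = w)

  hit_i <- pairs$i == i; hit_j <- pairs$j == i
  other <- c(pairs$j[hit_i], pairs$i[hit_j])
  ell <- c(pairs$ell[hit_i], pairs$ell[hit_j])
  wl <- c(w[hit_i], w[hit_j])
  Lm <- laplacian_matrix_test(L)
  frozen_obj <- function(y) {
    dif <- inst$Y[, other, drop = FALSE] - y
    sum((inst$X[, i] - inst$B %*% y)^2) +
      hp$alpha * drop(crossprod(y, Lm %*% y)) + hp$gamma * sum(y^2) +
      hp$beta * sum(wl * ell * colSums(dif * (M %*% dif)))
  }
  expect_lt(sqrt(sum(num_grad(frozen_obj, yi)^2)), 1e-5)
})

test_that("coding sweeps are idempotent without pairs and never increase the objective", {
  inst <- random_instance(74)
  hp <- srdml_hparams(alpha = 0.2, beta = 0, gamma = 0.1, tau = 1)
  L <- laplacian_of(inst$B, 2)
  no_pairs <- tibble::tibble(i = integer(0), j = integer(0), ell = integer(0))
  Y1 <- update_coding(inst$X, inst$B, inst$Y, inst$M, L, no_pairs, hp)
  Y2 <- update_coding(inst$X, inst$B, Y1, inst$M, L, no_pairs, hp)
  expect_equal(Y1, Y2, tolerance = 1e-10)

  for (seed in 81:100) {
    inst <- random_instance(seed)
    hp <- srdml_hparams(alpha = 0.15, beta = 0.4, gamma = 0.1, tau = 1.3, k_nn = 2)
    L <- laplacian_of(inst$B, 2)
    M <- psd_project(inst$M)
    pairs <- build_pairs(inst$labels)
    before <- srdml_objective(inst$X, inst$B, inst$Y, M, L, pairs, hp)$total
    Y_new <- suppressMessages(
      update_coding(inst$X, inst$B, inst$Y, M, L, pairs, hp)
    )
    after <- srdml_objective(inst$X, inst$B, Y_new, M, L, pairs, hp)$total
    expect_lte(after, before + 1e-9 * max(abs(before), 1))
  }
})

test_that("query encoding matches the ridge closed form and handles edge cases", {
  Q <- qr.Q(qr(withr::with_seed(32, matrix(rnorm(25), 5))))[, 1:3]
  y <- encode_query(Q[, 1], Q, gamma = 1e-10)
  expect_equal(y, c(1, 0, 0), tolerance = 1e-6)
  expect_equal(encode_query(rep(0, 5), Q, gamma = 0.1), rep(0, 3))
  expect_error(encode_query(rep(0, 4), Q, gamma = 0.1), "features")

  inst <- random_instance(75)
  hp <- srdml_hparams(gamma = 0.2, tau = 1)
  hp$alpha <- 0; hp$beta <- 0
  L <- matrix(0, 4, 4)
  no_pairs <- tibble::tibble(i = integer(0), j = integer(0), ell = integer(0))
  Ytr <- update_coding(inst$X, inst$B, inst$Y, inst$M, L, no_pairs, hp)
  expect_equal(encode_query(inst$X[, 5], inst$B, 0.2), Ytr[, 5], tolerance = 1e-10)
})
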