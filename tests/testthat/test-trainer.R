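test_that("objective matches scalar arithmetic on a hand-computed instance", {
  X <- matrix(c(1, 0, 0, 1), 2)
  B <- diag(2)
  Y <- matrix(c(0.5, 0, 0, 2), 2)
  M <- diag(2)
  L <- matrix(c(0.3, -0.3, -0.3, 0.3), 2)
  pairs <- tibble::tibble(i = 1L, j = 2L, ell = -1L)
  hp <- srdml_hparams(alpha = 0.5, beta = 2, gamma = 0.25, tau = 3, theta = 1)
  obj <- srdml_objective(X, B, Y, M, L, pairs, hp)
  # fidelity: (1-0.5)^2 + (1-2)^2 = 1.25
  expect_equal(obj$fidelity, 1.25, tolerance = 1e-12)
  # locality: Tr(Y'LY) = 0.3*(0.5-0)^2 + 0.3*(0-2)^2 = 1.275
  expect_equal(obj$locality, 0.5 * 1.275, tolerance = 1e-12)
  # pairwise: d2 = 0.25 + 4 = 4.25; Lambda = 1 + (3 - 4.25) = -0.25
  expect_equal(obj$pairwise, 2 * log1p(exp(-0.25)), tolerance = 1e-12)
  # ridge: 0.25 * (0.25 + 4)
  expect_equal(obj$ridge, 0.25 * 4.25, tolerance = 1e-12)
  expect_equal(obj$total, obj$fidelity + obj$locality + obj$pairwise + obj$ridge)

  # exact reconstruction with alpha = beta = 0 leaves only the ridge term
  hp0 <- hp; hp0$alpha <- 0; hp0$beta <- 0
  obj0 <- srdml_objective(B %*% Y, B, Y, M, L, pairs, hp0)
  expect_equal(obj0$total, 0.25 * sum(Y^2), tolerance = 1e-12)
  expect_true(all(unlist(obj) >= 0))
})

test_that("T_max = 0 returns the K-SVD / identity initialization unchanged", {
  fx <- get_fixtures()$tiny
  hp <- tiny_hp(T_max = 0, seed = 101, ksvd_sparsity = 2, ksvd_iters = 5)
  m <- srdml_fit(fx$data$features, hp)
  init <- ksvd_init(fx$data$features, K = 4, sparsity = 2, iters = 5, seed = 101)
  expect_identical(m$B, init$B)
  expect_identical(m$Y, init$Y)
  expect_equal(m$M, diag(4))
  expect_equal(nrow(m$trace), 1L)
  expect_equal(m$n_iter, 0L)
})

test_that("fitted models satisfy dictionary and metric invariants", {
  fx <- get_fixtures()$tiny
  m <- srdml_fit(fx$data$features, fx$hp)
  expect_lt(max(abs(sqrt(colSums(m$B^2)) - 1)), 1e-8)
  expect_lt(max(abs(m$M - t(m$M))), 1e-10)
  ev <- eigen(m$M, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-10)
  expect_lt(max(abs(rowSums(m$laplacian$L))), 1e-10)
  expect_true(all(is.finite(m$trace$objective)))
  expect_lte(nrow(m$trace), fx$hp$T_max + 1)
})

test_that("the objective trace is non-increasing on random instances", {
  for (seed in 1:5) {
    syn <- generate_synthetic(synthetic_spec(
      d = 6, K_true = 4, n_classes = 2, n_per_class = 4,
      atoms_per_class = 2, noise_sigma = 0.05, seed = seed
    ))
    m <- suppressMessages(suppressWarnings(
      srdml_fit(syn$features, tiny_hp(seed = seed))
    ))
    obj <- m$trace$objective
    expect_true(all(diff(obj) <= 1e-9 * pmax(abs(obj[-length(obj)]), 1)),
                label = sprintf("descent at seed %d", seed))
  }
})

test_that("fits with the same seed are bit-identical and containers round-trip", {
  fx <- get_fixtures()$tiny
  m1 <- srdml_fit(fx$data$features, fx$hp)
  m2 <- srdml_fit(fx$data$features, fx$hp)
  expect_identical(m1$B, m2$B)
  expect_identical(m1$Y, m2$Y)
  expect_identical(m1$M, m2$M)
  expect_identical(m1$trace, m2$trace)

  p1 <- withr::local_tempfile(fileext = ".rds")
  p2 <- withr::local_tempfile(fileext = ".rds")
  p3 <- withr::local_tempfile(fileext = ".rds")
  save_model(m1, p1)
  save_model(m2, p2)
  expect_identical(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))

  loaded <- load_model(p1)
  expect_identical(loaded$B, m1$B)
  expect_identical(loaded$hp$alpha, m1$hp$alpha)
  save_model(loaded, p3)   # save -> load -> save: identical bytes
  expect_identical(unname(tools::md5sum(p1)), unname(tools::md5sum(p3)))

  expect_error(load_model("no-such-model.rds"), "not found")
  bad <- withr::local_tempfile(fileext = ".rds")
  writeLines("not a model", bad)
  expect_error(load_model(bad), "corrupted|format")
})

test_that("single-class training disables the pairwise term with a warning", {
  syn <- generate_synthetic(synthetic_spec(
    d = 6, K_true = 4, n_classes = 2, n_per_class = 4,
    atoms_per_class = 2, noise_sigma = 0.05, seed = 7
  ))
  fm <- syn$features
  one_class <- feature_matrix(fm$X, labels = rep(1L, ncol(fm$X)), ids = fm$ids)
  expect_warning(m <- srdml_fit(one_class, tiny_hp(T_max = 2, seed = 7)),
                 "fewer than 2 classes")
  expect_equal(nrow(m$pairs), 0L)
  expect_equal(m$M, diag(4))   # no pairs: the metric never moves
})

test_that("with slack margins the pairwise term barely moves the codes", {
  # two tight, far-apart clusters: similar d2 ~ 0, dissimilar d2 >> tau + 1
  d <- 6; K <- 4
  inst <- random_instance(220, d = d, K = K, n = 8)
  Y0 <- matrix(0, K, 6)
  Y0[1, ] <- c(0, 0.01, 0.02, 50, 50.01, 50.02)
  labels <- c(1, 1, 1, 2, 2, 2)
  X <- inst$B %*% Y0
  pairs <- build_pairs(labels)
  L <- laplacian_of(inst$B, 2)
  hp <- srdml_hparams(alpha = 0.01, gamma = 0.01, tau = 100, theta = 1, beta = 0.5)
  Y_beta <- update_coding(X, inst$B, Y0, diag(K), L, pairs, hp)
  hp0 <- hp; hp0$beta <- 0
  Y_ridge <- update_coding(X, inst$B, Y0, diag(K), L, pairs, hp0)
  expect_lt(fnorm_test(Y_beta - Y_ridge), 1e-4 * max(1, fnorm_test(Y_ridge)))
})

test_that("tidy, glance and autoplot expose the training trace", {
  fx <- get_fixtures()$tiny
  m <- srdml_fit(fx$data$features, fx$hp)
  tr <- tidy(m)
  expect_s3_class(tr, "tbl_df")
  expect_true(all(c("iteration", "objective", "fidelity", "locality",
                    "pairwise", "ridge") %in% names(tr)))
  g <- glance(m)
  expect_equal(nrow(g), 1L)
  expect_equal(g$K, 4L)
  expect_equal(g$objective, tr$objective[nrow(tr)])
  p <- autoplot(m)
  expect_s3_class(p, "ggplot")
})
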