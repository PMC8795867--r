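#' Hyperparameters for SRDML training
#'
#' @param alpha Weight of the atom-locality (graph Laplacian) term.
#' @param beta Weight of the pairwise large-margin term.
#' @param gamma Ridge weight on the coding coefficients.
#' @param tau Pairwise threshold center; `NULL` (default) resolves at fit time
#'   to 1 + the median identity-metric squared distance over similar pairs of
#'   the initial codes, so similar pairs start near their margin.
#' @param theta Softplus sharpness (default 1, the reference setting).
#' @param k_nn Atom-graph neighbors (default 7, the best grid value reported
#'   for the locality term; clipped to K - 1 when K is small).
#' @param mu Atom-graph bandwidth or `"auto"` (median heuristic).
#' @param m_rank Effective rank bound of the metric (default `NULL` = K).
#' @param eta Weight of the `||M - I||^2` regularizer in the metric block.
#' @param xi Metric learning rate (backtracked).
#' @param T_max Maximum outer iterations of the alternating optimization.
#' @param K Dictionary size (default `NULL` = training-set size n, the
#'   reference protocol).
#' @param ksvd_sparsity Nonzeros per column for K-SVD initialization
#'   (default `NULL` = `max(1, round(K / 20))`).
#' @param ksvd_iters K-SVD initialization iterations (default 10).
#' @param n_pairs Maximum pairwise constraints (balanced sample when fewer
#'   than all pairs; default `Inf` = all pairs).
#' @param metric_steps Projected-gradient steps on M per outer iteration.
#' @param seed RNG seed threaded to initialization and pair sampling.
#' @param tol Relative objective-decrease threshold for early stopping.
#' @param patience Consecutive small-decrease iterations before stopping.
#' @return An `srdml_hparams` list.
#' @export
srdml_hparams <- function(alpha = 0.1, beta = 0.1, gamma = 0.01, tau = NULL,
                          theta = 1, k_nn = 7, mu = "auto", m_rank = NULL,
                          eta = 1, xi = 1e-3, T_max = 50, K = NULL,
                          ksvd_sparsity = NULL, ksvd_iters = 10,
                          n_pairs = Inf, metric_steps = 1, seed = 1,
                          tol = 1e-6, patience = 3) {
  hp <- list(
    alpha = alpha, beta = beta, gamma = gamma, tau = tau, theta = theta,
    k_nn = k_nn, mu = mu, m_rank = m_rank, eta = eta, xi = xi,
    T_max = T_max, K = K, ksvd_sparsity = ksvd_sparsity,
    ksvd_iters = ksvd_iters, n_pairs = n_pairs, metric_steps = metric_steps,
    seed = seed, tol = tol, patience = patience
  )
  for (f in c("alpha", "beta", "gamma", "eta", "xi", "theta")) {
    if (hp[[f]] < 0 || (f %in% c("eta", "xi", "theta") && hp[[f]] <= 0)) {
      srdml_stop(f, " must be positive")
    }
  }
  if (hp$T_max < 0) srdml_stop("T_max must be >= 0")
  structure(hp, class = "srdml_hparams")
}

#' @export
print.srdml_hparams <- function(x, ...) {
  cat("<srdml_hparams>\n")
  for (f in names(x)) {
    cat(sprintf("  %-14s %s\n", f, paste(format(x[[f]]), collapse = " ")))
  }
  invisible(x)
}

#' Joint SRDML objective and its term breakdown
#'
#' `||X - BY||_F^2 + alpha Tr(Y' L Y) + beta * pairwise_loss + gamma ||Y||_F^2`.
#'
#' @param X d x n matrix or [feature_matrix()].
#' @param B Dictionary. @param Y Coding matrix. @param M Metric.
#' @param L Atom Laplacian (matrix or [build_laplacian()] output).
#' @param pairs [build_pairs()] tibble.
#' @param hp [srdml_hparams()] with a resolved numeric `tau`.
#' @return List with `total`, `fidelity`, `locality`, `pairwise`, `ridge`
#'   (the last three already weighted by alpha, beta, gamma).
#' @export
srdml_objective <- function(X, B, Y, M, L, pairs, hp) {
  if (inherits(X, "feature_matrix")) X <- X$X
  fidelity <- sum((X - B %*% Y)^2)
  locality <- hp$alpha * locality_penalty(Y, L)
  pw <- if (hp$beta > 0) hp$beta * pairwise_loss(Y, M, pairs, hp$tau, hp$theta) else 0
  ridge <- hp$gamma * sum(Y^2)
  list(
    total = fidelity + locality + pw + ridge,
    fidelity = fidelity, locality = locality, pairwise = pw, ridge = ridge
  )
}

trace_row <- function(iter, obj, dB, dY, dM) {
  tibble::tibble(
    iteration = iter, objective = obj$total, fidelity = obj$fidelity,
    locality = obj$locality, pairwise = obj$pairwise, ridge = obj$ridge,
    delta_B = dB, delta_Y = dY, delta_M = dM
  )
}

#' Fit an SRDML model
#'
#' Alternating optimization: K-SVD initialization of (B, Y) with M = I, then
#' per outer iteration (1) closed-form dictionary update with compensating
#' row rescale of Y, (2) rebuild of the atom k-NN graph and Laplacian from the
#' new dictionary, (3) a Gauss-Seidel sweep of closed-form coefficient
#' updates, (4) projected-gradient metric update. Each block is accepted only
#' if the joint objective does not increase (the dictionary + Laplacian
#' rebuild is accepted or rejected as one proposal), so the recorded objective
#' trace is non-increasing. Stops early after `patience` consecutive
#' iterations with relative decrease below `tol`.
#'
#' @param X A [feature_matrix()] (or a d x n matrix, with `labels` supplied).
#' @param hp [srdml_hparams()].
#' @param labels Class labels when `X` is a bare matrix.
#' @return An `srdml_model`: list with `B`, `Y`, `M`, `laplacian`, `graph`,
#'   `pairs`, `hp` (with resolved `tau`, `K`, `m_rank`, `k_nn`), `labels`,
#'   `ids`, `trace` (tibble, one row per recorded state), `n_iter`,
#'   `converged`.
#' @examples
#' syn <- generate_synthetic(synthetic_spec(d = 8, K_true = 4, n_classes = 2,
#'   n_per_class = 6, atoms_per_class = 2, seed = 3))
#' fit <- srdml_fit(syn$features, srdml_hparams(K = 4, T_max = 3, seed = 3))
#' glance(fit)
#' @export
srdml_fit <- function(X, hp = srdml_hparams(), labels = NULL) {
  if (!inherits(X, "feature_matrix")) X <- feature_matrix(X, labels = labels)
  fm <- X
  X <- fm$X
  n <- ncol(X); d <- nrow(X)
  if (n < 2) warning("fewer than 2 training images: degenerate fit")
  hp$K <- hp$K %||% n
  K <- hp$K
  hp$m_rank <- hp$m_rank %||% K
  if (hp$m_rank < 1 || hp$m_rank > K) srdml_stop("m_rank must be in [1, K]")
  hp$ksvd_sparsity <- hp$ksvd_sparsity %||% max(1L, as.integer(round(K / 20)))
  if (hp$k_nn >= K) {
    hp$k_nn <- max(1L, K - 1L)
    warning("k_nn clipped to K - 1 = ", hp$k_nn)
  }

  classes <- unique(fm$labels[!is.na(fm$labels)])
  beta_eff <- hp$beta
  if (length(classes) < 2 && hp$beta > 0) {
    warning("fewer than 2 classes: disabling the pairwise term (beta = 0)")
    hp$beta <- 0
  }

  init <- ksvd_init(X, K, hp$ksvd_sparsity, iters = hp$ksvd_iters, seed = hp$seed)
  B <- init$B
  Y <- init$Y
  M <- diag(K)
  pairs <- if (hp$beta > 0) {
    build_pairs(fm$labels, max_pairs = hp$n_pairs, seed = hp$seed)
  } else {
    tibble::tibble(i = integer(0), j = integer(0), ell = integer(0))
  }
  hp$tau <- hp$tau %||% tau_default(Y, pairs)

  graph <- build_atom_graph(B, hp$k_nn, hp$mu)
  lap <- build_laplacian(graph)
  obj <- srdml_objective(X, B, Y, M, lap, pairs, hp)
  if (!is.finite(obj$total)) srdml_stop("non-finite objective at initialization")
  trace <- trace_row(0L, obj, NA_real_, NA_real_, NA_real_)

  stall <- 0L
  t_done <- 0L
  if (hp$T_max >= 1) {
    for (t in seq_len(hp$T_max)) {
      prev_total <- obj$total
      # (1)+(2) dictionary update and graph rebuild, accepted jointly
      upd <- update_dictionary(X, Y)
      graph_try <- build_atom_graph(upd$B, hp$k_nn, hp$mu)
      lap_try <- build_laplacian(graph_try)
      obj_try <- srdml_objective(X, upd$B, upd$Y, M, lap_try, pairs, hp)
      dB <- fnorm(upd$B - B)
      if (obj_try$total <= obj$total + 1e-9 * max(abs(obj$total), 1)) {
        B <- upd$B; Y <- upd$Y; graph <- graph_try; lap <- lap_try; obj <- obj_try
      } else {
        dB <- 0
      }
      if (!is.finite(obj$total)) srdml_stop("non-finite objective after dictionary update")

      # (3) coefficient sweep (internally damped/reverted to preserve descent)
      Y_new <- update_coding(X, B, Y, M, lap, pairs, hp)
      dY <- fnorm(Y_new - Y)
      Y <- Y_new
      obj <- srdml_objective(X, B, Y, M, lap, pairs, hp)
      if (!is.finite(obj$total)) srdml_stop("non-finite objective after coding update")

      # (4) metric update (backtracked on the block and pairwise objectives)
      M_new <- update_metric(Y, M, pairs, hp)
      dM <- fnorm(M_new - M)
      M <- M_new
      obj_new <- srdml_objective(X, B, Y, M, lap, pairs, hp)
      if (!is.finite(obj_new$total)) srdml_stop("non-finite objective after metric update")

      trace <- dplyr::bind_rows(trace, trace_row(t, obj_new, dB, dY, dM))
      rel <- (prev_total - obj_new$total) / max(abs(prev_total), 1e-12)
      obj <- obj_new
      t_done <- t
      stall <- if (rel < hp$tol) stall + 1L else 0L
      if (stall >= hp$patience) break
    }
  }
  hp$beta <- beta_eff

  structure(list(
    B = B, Y = Y, M = M, laplacian = lap, graph = graph, pairs = pairs,
    hp = hp, labels = fm$labels, ids = fm$ids, trace = trace,
    n_iter = t_done, converged = stall >= hp$patience,
    format_version = 1L
  ), class = "srdml_model")
}

#' @export
print.srdml_model <- function(x, ...) {
  cat(sprintf(
    "<srdml_model> d = %d, n = %d, K = %d | %d outer iteration(s)%s\n",
    nrow(x$B), ncol(x$Y), ncol(x$B), x$n_iter,
    if (x$converged) " (early stop)" else ""
  ))
  cat(sprintf("  objective %.6g -> %.6g\n",
              x$trace$objective[1], utils::tail(x$trace$objective, 1)))
  invisible(x)
}

validate_model <- function(model) {
  if (!inherits(model, "srdml_model")) srdml_stop("not an srdml_model")
  need <- c("B", "Y", "M", "laplacian", "hp", "labels", "ids", "trace")
  miss <- setdiff(need, names(model))
  if (length(miss)) srdml_stop("model container missing field(s): ",
                               paste(miss, collapse = ", "))
  if (max(abs(sqrt(colSums(model$B^2)) - 1)) > 1e-6) {
    srdml_stop("dictionary columns are not unit norm")
  }
  if (max(abs(model$M - t(model$M))) > 1e-8) srdml_stop("metric is not symmetric")
  ev <- eigen(model$M, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1)) srdml_stop("metric is not PSD")
  invisible(model)
}

#' Save / load a trained SRDML model
#'
#' Models persist as an uncompressed native R serialization (version 3), so
#' identical models produce byte-identical files; all arrays and
#' hyperparameters round-trip exactly. `load_model()` validates the container
#' (format version, dictionary and metric invariants) before returning.
#'
#' @param model An `srdml_model`. @param path Destination / source path.
#' @return `save_model()` invisibly returns `path`; `load_model()` returns the
#'   validated model.
#' @export
save_model <- function(model, path) {
  validate_model(model)
  saveRDS(model, path, version = 3, compress = FALSE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) srdml_stop("model file not found: ", path)
  model <- tryCatch(readRDS(path), error = function(e) {
    srdml_stop("corrupted model container: ", conditionMessage(e))
  })
  if (!identical(model$format_version, 1L)) {
    srdml_stop("unsupported model format version: ",
               format(model$format_version))
  }
  validate_model(model)
  model
}
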