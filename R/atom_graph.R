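#' Build the k-nearest-neighbor similarity graph over dictionary atoms
#'
#' Edge weights are Gaussian in squared Euclidean atom distance,
#' `P_ij = exp(-||b_i - b_j||^2 / mu)` when atom j is among the `k_nn` nearest
#' atoms of atom i (self excluded), else 0. The directed k-NN relation is
#' symmetrized with the elementwise maximum (union of neighborhoods), which
#' preserves every stated neighbor weight and yields a valid Laplacian.
#'
#' @param B d x K dictionary (or `ksvd_init()`-style list with element `B`).
#' @param k_nn Neighbors per atom, `1 <= k_nn < K`.
#' @param mu Gaussian bandwidth, or `"auto"` (default): the median of squared
#'   distances over selected neighbor pairs.
#' @return An `atom_graph`: list with `P` (symmetric nonnegative K x K weight
#'   matrix, zero diagonal), `k_nn`, `mu` (resolved value).
#' @export
build_atom_graph <- function(B, k_nn, mu = "auto") {
  if (is.list(B) && !is.null(B$B)) B <- B$B
  K <- ncol(B)
  if (k_nn < 1 || k_nn >= K) srdml_stop("k_nn must satisfy 1 <= k_nn < K (K = ", K, ")")
  D2 <- as.matrix(stats::dist(t(B)))^2
  sel <- matrix(FALSE, K, K)
  for (i in seq_len(K)) {
    d <- D2[i, ]
    d[i] <- Inf
    nb <- order(d, seq_len(K))[seq_len(k_nn)]   # ties broken by index
    sel[i, nb] <- TRUE
  }
  if (identical(mu, "auto")) {
    mu <- stats::median(D2[sel])
    if (!is.finite(mu) || mu <= 0) mu <- max(mean(D2[sel]), 1e-12)
  }
  if (mu <= 0) srdml_stop("mu must be positive")
  P <- matrix(0, K, K)
  P[sel] <- exp(-D2[sel] / mu)
  P <- pmax(P, t(P))
  diag(P) <- 0
  structure(list(P = P, k_nn = as.integer(k_nn), mu = mu), class = "atom_graph")
}

#' Graph Laplacian of an atom graph
#'
#' `L = W - P` with `W = diag(rowSums(P))`. Row sums of L are zero and L is
#' symmetric positive semidefinite for any symmetric nonnegative P.
#'
#' @param graph An [build_atom_graph()] result, or a symmetric nonnegative
#'   weight matrix.
#' @return An `atom_laplacian`: list with `L` (K x K) and `degrees`.
#' @export
build_laplacian <- function(graph) {
  P <- if (inherits(graph, "atom_graph")) graph$P else as.matrix(graph)
  if (any(P < 0)) srdml_stop("weight matrix must be nonnegative")
  if (max(abs(P - t(P))) > 1e-10) {
    srdml_stop("weight matrix must be symmetric (symmetrize upstream)")
  }
  degrees <- rowSums(P)
  L <- diag(degrees, nrow(P)) - P
  structure(list(L = L, degrees = degrees), class = "atom_laplacian")
}

# Accept an atom_laplacian object or a plain matrix.
laplacian_matrix <- function(L) {
  if (inherits(L, "atom_laplacian")) L$L else as.matrix(L)
}

#' Atom-locality penalty
#'
#' `Tr(Y' L Y)`, equal to `0.5 * sum_ij P_ij ||row_i(Y) - row_j(Y)||^2`:
#' coefficient profiles of atoms linked in the graph are pulled together.
#'
#' @param Y K x n coding matrix.
#' @param L [build_laplacian()] result or K x K Laplacian matrix.
#' @return Nonnegative scalar.
#' @export
locality_penalty <- function(Y, L) {
  Lm <- laplacian_matrix(L)
  if (nrow(Y) != nrow(Lm)) {
    srdml_stop("Y has ", nrow(Y), " rows but Laplacian is ", nrow(Lm), " x ", ncol(Lm))
  }
  sum(Y * (Lm %*% Y))
}

#' Export an atom graph as a tidy edge list
#'
#' @param graph An [build_atom_graph()] result.
#' @return Tibble with columns `i`, `j`, `weight` (upper triangle, w > 0).
#' @export
graph_edges <- function(graph) {
  stopifnot(inherits(graph, "atom_graph"))
  idx <- which(upper.tri(graph$P) & graph$P > 0, arr.ind = TRUE)
  tibble::tibble(i = idx[, 1], j = idx[, 2], weight = graph$P[idx])
}
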