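#' Tidy the optimization trace of a fitted SRDML model
#'
#' @param x An `srdml_model`.
#' @param ... Unused.
#' @return A tibble with one row per recorded outer iteration (iteration 0 is
#'   the K-SVD / identity initialization): the joint objective, its four
#'   terms, and the Frobenius step sizes of B, Y and M.
#' @export
tidy.srdml_model <- function(x, ...) {
  x$trace
}

#' One-row summary of a fitted SRDML model
#'
#' @inheritParams tidy.srdml_model
#' @return A one-row tibble: problem sizes, iterations, convergence flag,
#'   final objective and its terms, and the effective metric rank.
#' @export
glance.srdml_model <- function(x, ...) {
  last <- x$trace[nrow(x$trace), ]
  ev <- eigen(x$M, symmetric = TRUE, only.values = TRUE)$values
  tibble::tibble(
    d = nrow(x$B), n = ncol(x$Y), K = ncol(x$B),
    n_iter = x$n_iter, converged = x$converged,
    objective = last$objective, fidelity = last$fidelity,
    locality = last$locality, pairwise = last$pairwise, ridge = last$ridge,
    metric_rank = sum(ev > 1e-10 * max(ev, 1e-300)),
    tau = x$hp$tau
  )
}

#' Plot the objective trace of a fitted SRDML model
#'
#' @param object An `srdml_model`.
#' @param ... Unused.
#' @return A ggplot: joint objective and its terms per outer iteration.
#' @export
autoplot.srdml_model <- function(object, ...) {
  tr <- object$trace |>
    tidyr_pivot()
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$iteration, y = .data$value,
                                   colour = .data$term)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "outer iteration", y = "objective value",
                  colour = NULL, title = "SRDML alternating optimization") +
    ggplot2::theme_minimal()
}

# small local reshape (avoids importing tidyr for one call)
tidyr_pivot <- function(trace) {
  terms <- c("objective", "fidelity", "locality", "pairwise", "ridge")
  purrr::map_dfr(terms, function(tm) {
    tibble::tibble(iteration = trace$iteration, term = tm, value = trace[[tm]])
  })
}

#' Plot cross-validated retrieval metrics
#'
#' @param object The tibble returned by [cross_validate()].
#' @param ... Unused.
#' @return A ggplot of per-fold mAP and Prec\@n by query class.
#' @export
autoplot.srdml_cv <- function(object, ...) {
  metric_cols <- setdiff(names(object), c("fold", "query_class", "n_queries"))
  df <- object |>
    dplyr::filter(!.data$fold %in% c("mean", "sd"))
  long <- purrr::map_dfr(metric_cols, function(m) {
    tibble::tibble(fold = df$fold, query_class = df$query_class,
                   metric = m, value = df[[m]])
  })
  ggplot2::ggplot(long, ggplot2::aes(x = .data$query_class, y = .data$value,
                                     colour = .data$metric)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::labs(x = "query class", y = "percent", colour = NULL,
                  title = "Cross-validated retrieval performance") +
    ggplot2::theme_minimal()
}
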