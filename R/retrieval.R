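#' Rank database images against a query by metric distance
#'
#' Computes the squared Mahalanobis distance between the query code and every
#' database code and sorts ascending, breaking ties by ascending database
#' index (stable).
#'
#' @param query_code Length-K code vector (see [encode_query()]).
#' @param db_codes K x N coding matrix of the database.
#' @param M K x K metric matrix.
#' @param db_ids,db_labels Optional identifiers / labels for database columns.
#' @param query_id,query_label Optional query identifier / label; when both
#'   labels are present a `relevant` flag (same label) is included.
#' @return A tibble, one row per database image in retrieval order, with
#'   columns `rank`, `index`, `distance`, and optionally `id`, `label`,
#'   `relevant`. The query id is attached as attribute `query_id`.
#' @export
rank_database <- function(query_code, db_codes, M, db_ids = NULL,
                          db_labels = NULL, query_id = NULL,
                          query_label = NULL) {
  db_codes <- as.matrix(db_codes)
  if (ncol(db_codes) == 0) srdml_stop("empty retrieval database")
  if (length(query_code) != nrow(db_codes)) {
    srdml_stop("query code length ", length(query_code),
               " does not match database code length ", nrow(db_codes))
  }
  D <- db_codes - query_code
  d2 <- colSums(D * (M %*% D))
  ord <- order(d2, seq_along(d2))
  out <- tibble::tibble(
    rank = seq_along(ord), index = ord, distance = d2[ord]
  )
  if (!is.null(db_ids)) out$id <- db_ids[ord]
  if (!is.null(db_labels)) {
    out$label <- db_labels[ord]
    if (!is.null(query_label)) out$relevant <- as.integer(out$label == query_label)
  }
  attr(out, "query_id") <- query_id
  out
}

#' Average precision of one ranking
#'
#' `AP = (1/R) * sum_{i=1..R} i / rank(i)`, where `rank(i)` is the 1-based
#' position of the i-th relevant item and R is the number of relevant items in
#' the database. This equals the mean of precision values at the relevant
#' ranks (precision at the i-th relevant item is exactly `i / rank(i)`).
#'
#' @param relevance Binary (0/1) relevance flags in rank order.
#' @param n_relevant Number of relevant items in the database (default: the
#'   number of 1s in `relevance`; pass explicitly for truncated rankings).
#' @return Scalar in \[0, 1\], or NA with a warning when `n_relevant` is 0.
#' @examples
#' average_precision(c(1, 0, 1, 0)) # (1/1 + 2/3) / 2
#' @export
average_precision <- function(relevance, n_relevant = sum(relevance)) {
  if (n_relevant < 1) {
    warning("query has no relevant items; AP undefined")
    return(NA_real_)
  }
  ranks <- which(relevance == 1)
  if (length(ranks) == 0) return(0)
  sum(seq_along(ranks) / ranks) / n_relevant
}

rank_relevance <- function(res) {
  if (is.data.frame(res)) {
    if (!"relevant" %in% names(res)) srdml_stop("ranking lacks a 'relevant' column")
    res$relevant
  } else {
    res
  }
}

#' Mean average precision over a set of queries
#'
#' @param results List of [rank_database()] tibbles with a `relevant` column
#'   (or of plain binary relevance vectors).
#' @return Mean AP over queries with at least one relevant item.
#' @export
mean_average_precision <- function(results) {
  aps <- vapply(results, function(r) {
    rel <- rank_relevance(r)
    suppressWarnings(average_precision(rel))
  }, numeric(1))
  if (all(is.na(aps))) srdml_stop("no scorable queries (no relevant items)")
  if (anyNA(aps)) warning(sum(is.na(aps)), " query(ies) skipped: no relevant items")
  mean(aps, na.rm = TRUE)
}

#' Precision at a rank cutoff
#'
#' Mean over queries of the fraction of the top-`n` retrieved items sharing
#' the query's class. Rankings shorter than `n` are scored over their
#' available length, with a warning.
#'
#' @inheritParams mean_average_precision
#' @param n Rank cutoff (>= 1).
#' @return Scalar in \[0, 1\].
#' @export
precision_at_n <- function(results, n) {
  if (n < 1) srdml_stop("n must be >= 1")
  vals <- vapply(results, function(r) {
    rel <- rank_relevance(r)
    if (length(rel) < n) {
      warning("ranking shorter than cutoff n = ", n, "; using available length")
      n <- length(rel)
    }
    mean(rel[seq_len(n)])
  }, numeric(1))
  mean(vals)
}

#' Label-stratified fold assignment
#'
#' Shuffles within each class (seeded) and deals fold labels round-robin, so
#' per-class counts differ by at most one across folds.
#'
#' @param labels Class labels, length n.
#' @param n_folds Number of folds (default 5).
#' @param seed RNG seed.
#' @return Integer vector of fold assignments in 1..n_folds.
#' @export
stratified_folds <- function(labels, n_folds = 5, seed = 1) {
  n <- length(labels)
  folds <- integer(n)
  withr::with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      if (length(idx) < n_folds) {
        srdml_stop("class ", cl, " has ", length(idx),
                   " members: fewer than n_folds = ", n_folds)
      }
      idx <- sample(idx)
      folds[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  folds
}

score_queries <- function(results, top_n) {
  out <- tibble::tibble(map = 100 * mean_average_precision(results))
  for (n in top_n) out[[sprintf("prec%d", n)]] <- 100 * precision_at_n(results, n)
  out
}

#' Stratified k-fold cross-validated retrieval evaluation
#'
#' For each fold: train on the other folds with [srdml_fit()], ridge-code the
#' held-out images as queries, rank each query against the training database
#' (queries are never ranked against other held-out images), and score mAP and
#' Prec\@n per query class and overall. Metrics are reported in percent.
#'
#' @param X A [feature_matrix()] with labels.
#' @param hp [srdml_hparams()].
#' @param n_folds Number of folds (default 5).
#' @param seed Seed for the stratified split (the fit seed comes from `hp`).
#' @param top_n Cutoffs for Prec\@n (default c(10, 20)).
#' @return A tibble of class `srdml_cv` with columns `fold` (fold number, or
#'   `"mean"` / `"sd"` summary rows), `query_class` (class label or `"all"`),
#'   `n_queries`, `map`, `prec<n>`. Fold assignments are attached as attribute
#'   `folds`.
#' @export
cross_validate <- function(X, hp = srdml_hparams(), n_folds = 5, seed = 1,
                           top_n = c(10, 20)) {
  stopifnot(inherits(X, "feature_matrix"))
  if (anyNA(X$labels)) srdml_stop("cross-validation requires labels for every image")
  folds <- stratified_folds(X$labels, n_folds, seed)
  per_fold <- purrr::map_dfr(seq_len(n_folds), function(f) {
    tr <- which(folds != f)
    te <- which(folds == f)
    fm_tr <- feature_matrix(X$X[, tr, drop = FALSE], X$labels[tr], X$ids[tr])
    model <- srdml_fit(fm_tr, hp)
    Q <- encode_query(X$X[, te, drop = FALSE], model$B, model$hp$gamma)
    Q <- as.matrix(Q)
    results <- lapply(seq_along(te), function(q) {
      rank_database(Q[, q], model$Y, model$M,
                    db_ids = model$ids, db_labels = model$labels,
                    query_id = X$ids[te[q]], query_label = X$labels[te[q]])
    })
    qlab <- X$labels[te]
    groups <- c(list(all = seq_along(te)),
                split(seq_along(te), qlab))
    purrr::imap_dfr(groups, function(qs, cls) {
      dplyr::bind_cols(
        tibble::tibble(fold = as.character(f), query_class = as.character(cls),
                       n_queries = length(qs)),
        score_queries(results[qs], top_n)
      )
    })
  })
  metric_cols <- c("map", sprintf("prec%d", top_n))
  summary_rows <- per_fold |>
    dplyr::group_by(.data$query_class) |>
    dplyr::summarise(
      n_queries = sum(.data$n_queries),
      dplyr::across(dplyr::all_of(metric_cols),
                    list(mean = mean, sd = stats::sd)),
      .groups = "drop"
    )
  mk <- function(stat) {
    out <- tibble::tibble(fold = stat, query_class = summary_rows$query_class,
                          n_queries = summary_rows$n_queries)
    for (m in metric_cols) out[[m]] <- summary_rows[[paste0(m, "_", stat)]]
    out
  }
  res <- dplyr::bind_rows(per_fold, mk("mean"), mk("sd")) |>
    dplyr::arrange(.data$query_class)
  attr(res, "folds") <- folds
  class(res) <- c("srdml_cv", class(res))
  res
}
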