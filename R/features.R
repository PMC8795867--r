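#' Labeled feature matrix
#'
#' Container for a d x n feature matrix (one column per image) with an integer
#' class label and an identifier per image. All srdml training and evaluation
#' functions accept this container; [as_feature_tibble()] converts to a tidy
#' one-row-per-image tibble and [feature_matrix()] accepts such a tibble back.
#'
#' @param x Either a numeric matrix with d rows (features) and n columns
#'   (images), or a data frame with an `id` column, feature columns, and a
#'   `label` column (one row per image, as written by [write_features()]).
#' @param labels Integer-like class labels, length n. Ignored when `x` is a
#'   data frame. May contain NA when labels are unknown (e.g. query-only sets).
#' @param ids Character identifiers, length n; defaults to column names of `x`
#'   or `img<i>`.
#' @return An object of class `feature_matrix`: a list with elements `X`
#'   (d x n numeric matrix), `labels` (integer), `ids` (character).
#' @examples
#' fm <- feature_matrix(matrix(rnorm(20), 4), labels = c(1, 1, 2, 2, 2))
#' dim(fm$X)
#' @export
feature_matrix <- function(x, labels = NULL, ids = NULL) {
  if (is.data.frame(x)) {
    if (!all(c("id", "label") %in% names(x))) {
      srdml_stop("data-frame input needs 'id' and 'label' columns")
    }
    feat_cols <- setdiff(names(x), c("id", "label"))
    X <- t(as.matrix(x[, feat_cols, drop = FALSE]))
    rownames(X) <- feat_cols
    return(feature_matrix(X, labels = x$label, ids = as.character(x$id)))
  }
  X <- as.matrix(x)
  storage.mode(X) <- "double"
  if (ncol(X) < 1L) srdml_stop("feature matrix needs at least one column (image)")
  if (anyNA(X) || any(!is.finite(X))) srdml_stop("feature matrix contains non-finite entries")
  n <- ncol(X)
  if (is.null(labels)) labels <- rep(NA_integer_, n)
  labels <- as.integer(labels)
  if (length(labels) != n) srdml_stop("labels must have length ", n, " (one per column)")
  if (is.null(ids)) ids <- colnames(X) %||% sprintf("img%04d", seq_len(n))
  ids <- as.character(ids)
  if (length(ids) != n) srdml_stop("ids must have length ", n)
  structure(list(X = X, labels = labels, ids = ids), class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf(
    "<feature_matrix> %d features x %d images, %d class(es)\n",
    nrow(x$X), ncol(x$X), length(unique(x$labels[!is.na(x$labels)]))
  ))
  invisible(x)
}

#' @rdname feature_matrix
#' @param fm A `feature_matrix`.
#' @export
as_feature_tibble <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  feats <- as.data.frame(t(fm$X))
  names(feats) <- sprintf("f%d", seq_len(nrow(fm$X)))
  dplyr::bind_cols(tibble::tibble(id = fm$ids), tibble::as_tibble(feats),
                   tibble::tibble(label = fm$labels))
}

#' Read and write labeled features as CSV
#'
#' The on-disk layout is one row per image: a header row, then columns
#' `id, f1, ..., fd, label`. Values round-trip to at least 12 significant
#' digits.
#'
#' @param path File path.
#' @return `read_features()` returns a [feature_matrix()];
#'   `write_features()` invisibly returns `path`.
#' @export
read_features <- function(path) {
  if (!file.exists(path)) srdml_stop("feature file not found: ", path)
  if (file.size(path) == 0) srdml_stop("feature file is empty: ", path)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(df) == 0) srdml_stop("feature file has no rows: ", path)
  if (!all(c("id", "label") %in% names(df))) {
    srdml_stop("feature CSV must have 'id' and 'label' columns: ", path)
  }
  feat_cols <- setdiff(names(df), c("id", "label"))
  if (anyNA(df[feat_cols])) {
    row <- which(rowSums(is.na(df[feat_cols])) > 0)[1]
    srdml_stop("missing feature value at row ", row, " of ", path)
  }
  bad <- !vapply(df[feat_cols], is.numeric, logical(1))
  if (any(bad)) {
    srdml_stop("non-numeric feature column(s): ", paste(feat_cols[bad], collapse = ", "))
  }
  feature_matrix(as.data.frame(df))
}

#' @rdname read_features
#' @param fm A [feature_matrix()].
#' @export
write_features <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  readr::write_csv(as_feature_tibble(fm), path, progress = FALSE)
  invisible(path)
}
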