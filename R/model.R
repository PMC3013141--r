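# Cosine-distance nearest-neighbour classifier, jackknife evaluation and
# incremental feature selection.
#
# Distance between samples u, v is D(u, v) = 1 - (u . v) / (|u| |v|),
# i.e. one minus the cosine similarity, in [0, 2]. A query takes the class
# of its nearest training sample; jackknife (leave-one-out) predicts each
# sample from the remaining n - 1. IFS evaluates the nested prefixes
# S_1 c S_2 c ... of a ranked feature list and picks the prefix whose
# jackknife accuracy peaks.

#' Cosine distance between two sample vectors
#'
#' @param u,v Equal-length numeric vectors, each with nonzero norm.
#' @return `1 - cos(angle)`, in \[0, 2\]; 0 for identical directions.
#' @export
nna_distance <- function(u, v) {
  if (length(u) != length(v)) stop_hx("vectors must have equal dimension")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop_hx("cosine distance undefined for zero-norm vector")
  1 - sum(u * v) / (nu * nv)
}

#' Nearest-neighbour class prediction
#'
#' Each query takes the label of its minimum-cosine-distance training
#' sample; exact distance ties resolve to the lowest training-sample index.
#'
#' @param query Numeric vector or matrix (queries in rows) over the same
#'   feature columns as `train`.
#' @param train A `feature_matrix` of labelled training samples.
#' @param feature_columns Optional integer subset of feature columns to use.
#' @return Tibble with `label` (predicted), `nn_index`, `nn_id`, `distance`.
#' @export
nna_predict <- function(query, train, feature_columns = NULL) {
  Q <- if (is.matrix(query)) query else matrix(query, nrow = 1L)
  Xt <- train$values
  if (!is.null(feature_columns)) {
    Xt <- Xt[, feature_columns, drop = FALSE]
    if (ncol(Q) == ncol(train$values)) Q <- Q[, feature_columns, drop = FALSE]
  }
  if (ncol(Q) != ncol(Xt)) stop_hx("query dimension mismatch with training features")
  if (nrow(Xt) == 0L) stop_hx("training set is empty")
  sim <- cosine_similarity(Q, Xt)
  nn <- max.col(sim, ties.method = "first")
  tibble::tibble(label = as.character(train$labels[nn]),
                 nn_index = nn,
                 nn_id = train$sample_id[nn],
                 distance = 1 - sim[cbind(seq_len(nrow(Q)), nn)])
}

# Batch cosine similarity. A zero-norm row (possible at small feature
# prefixes, e.g. a single integer PSSM score of 0) has no direction; it is
# assigned similarity 0 with everything, i.e. treated as uncorrelated. The
# strict two-vector nna_distance() keeps its error instead.
cosine_similarity <- function(A, B) {
  na <- sqrt(rowSums(A^2)); nb <- sqrt(rowSums(B^2))
  za <- na == 0; zb <- nb == 0
  sim <- (A %*% t(B)) / outer(pmax(na, 1), pmax(nb, 1))
  if (any(za)) sim[za, ] <- 0
  if (any(zb)) sim[, zb] <- 0
  pmin(pmax(sim, -1), 1)  # guard rounding past +/-1
}

#' Evaluation metrics from confusion counts
#'
#' `Sn = TP/(TP+FN)`, `Sp = TN/(TN+FP)`, `AC = (TP+TN)/n` and
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`. A zero MCC
#' denominator (a degenerate confusion margin) yields `MCC = 0` with a
#' message; an empty class yields `NA` for the corresponding rate.
#'
#' @param counts Named list/vector with `TP`, `FP`, `TN`, `FN`.
#' @return One-row tibble: `TP`, `FP`, `TN`, `FN`, `Sn`, `Sp`, `AC`, `MCC`.
#' @export
compute_metrics <- function(counts) {
  tp <- as.numeric(counts[["TP"]]); fp <- as.numeric(counts[["FP"]])
  tn <- as.numeric(counts[["TN"]]); fn <- as.numeric(counts[["FN"]])
  if (any(c(tp, fp, tn, fn) < 0)) stop_hx("confusion counts must be non-negative")
  n <- tp + fp + tn + fn
  if (n == 0) stop_hx("confusion counts are all zero")
  sn <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  sp <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom > 0) (tp * tn - fp * fn) / sqrt(denom) else {
    message("compute_metrics: degenerate confusion margin; MCC set to 0")
    0
  }
  tibble::tibble(TP = tp, FP = fp, TN = tn, FN = fn,
                 Sn = sn, Sp = sp, AC = (tp + tn) / n, MCC = mcc)
}

#' Jackknife (leave-one-out) evaluation of the NNA classifier
#'
#' Each sample is removed in turn and predicted by the nearest-neighbour
#' rule over the remaining samples, restricted to `feature_columns`.
#'
#' @param fm A `feature_matrix` with both classes present.
#' @param feature_columns Integer columns to use (default all).
#' @return One-row metrics tibble as from [compute_metrics()].
#' @export
jackknife_nna <- function(fm, feature_columns = NULL) {
  X <- fm$values
  if (!is.null(feature_columns)) X <- X[, feature_columns, drop = FALSE]
  n <- nrow(X)
  if (n < 2L) stop_hx("jackknife needs at least 2 samples")
  if (dplyr::n_distinct(fm$labels) < 2L) stop_hx("both classes must be present")
  sim <- cosine_similarity(X, X)
  diag(sim) <- -Inf
  nn <- max.col(sim, ties.method = "first")
  confusion_metrics(fm$labels, fm$labels[nn])
}

confusion_metrics <- function(truth, pred) {
  compute_metrics(list(
    TP = sum(truth == "positive" & pred == "positive"),
    FP = sum(truth == "negative" & pred == "positive"),
    TN = sum(truth == "negative" & pred == "negative"),
    FN = sum(truth == "positive" & pred == "negative")))
}

#' Incremental feature selection over a ranked list
#'
#' Evaluates the jackknife NNA on every nested prefix S_k = first k ranked
#' features, k = 1..`max_k`, and selects the optimum. Accuracy is the
#' selection objective by default (`objective = "MCC"` is available); ties
#' resolve to the smallest k (fewer features, same performance). The
#' similarity matrix is updated incrementally across k, so the whole curve
#' costs O(max_k n^2).
#'
#' @param fm A `feature_matrix`.
#' @param ranked A `ranked_features` list (or integer column vector).
#' @param max_k Longest prefix to evaluate (default: the whole list).
#' @param objective `"AC"` (default) or `"MCC"`.
#' @return An `ifs_result`: list with `per_k` (tibble of k, TP..MCC),
#'   `optimal_k`, `optimal_metrics`, `objective`, `feature_columns`
#'   (the selected prefix), `ranked`.
#' @export
run_ifs <- function(fm, ranked, max_k = NULL, objective = c("AC", "MCC")) {
  objective <- match.arg(objective)
  cols <- if (is.numeric(ranked)) as.integer(ranked) else ranked$column
  max_k <- if (is.null(max_k)) length(cols)
           else min(assert_scalar_count(max_k, "max_k"), length(cols))
  n <- nrow(fm$values)
  if (n < 2L) stop_hx("jackknife needs at least 2 samples")
  if (dplyr::n_distinct(fm$labels) < 2L) stop_hx("both classes must be present")

  G <- matrix(0, n, n)       # running Gram matrix over the prefix
  ns <- numeric(n)           # running squared norms
  rows <- vector("list", max_k)
  for (k in seq_len(max_k)) {
    v <- fm$values[, cols[k]]
    G <- G + tcrossprod(v)
    ns <- ns + v^2
    z <- ns == 0  # zero-norm rows: similarity 0, as in cosine_similarity()
    sim <- G / sqrt(outer(pmax(ns, 1), pmax(ns, 1)))
    if (any(z)) { sim[z, ] <- 0; sim[, z] <- 0 }
    diag(sim) <- -Inf
    nn <- max.col(sim, ties.method = "first")
    rows[[k]] <- confusion_metrics(fm$labels, fm$labels[nn])
  }
  per_k <- dplyr::bind_rows(rows)
  per_k <- tibble::add_column(per_k, k = seq_len(max_k), .before = 1L)
  opt <- which.max(per_k[[objective]])  # first max = smallest k
  structure(list(per_k = per_k,
                 optimal_k = per_k$k[opt],
                 optimal_metrics = per_k[opt, ],
                 objective = objective,
                 feature_columns = cols[seq_len(per_k$k[opt])],
                 ranked = ranked),
            class = "ifs_result")
}

#' @export
print.ifs_result <- function(x, ...) {
  m <- x$optimal_metrics
  cat(sprintf("<ifs_result> %d prefixes evaluated; optimum k = %d (Sn %.3f, Sp %.3f, AC %.3f, MCC %.3f)\n",
              nrow(x$per_k), x$optimal_k, m$Sn, m$Sp, m$AC, m$MCC))
  invisible(x)
}

#' Tidy the per-prefix IFS curve
#'
#' @param x An `ifs_result`.
#' @param ... Unused.
#' @return Tibble with one row per evaluated prefix size `k` and columns
#'   `TP`, `FP`, `TN`, `FN`, `Sn`, `Sp`, `AC`, `MCC`.
#' @export
tidy.ifs_result <- function(x, ...) x$per_k

#' One-row summary of an IFS fit
#'
#' @inheritParams tidy.ifs_result
#' @return One-row tibble: `optimal_k`, `Sn`, `Sp`, `AC`, `MCC`,
#'   `n_evaluated`, `objective`.
#' @export
glance.ifs_result <- function(x, ...) {
  m <- x$optimal_metrics
  tibble::tibble(optimal_k = x$optimal_k, Sn = m$Sn, Sp = m$Sp, AC = m$AC,
                 MCC = m$MCC, n_evaluated = nrow(x$per_k),
                 objective = x$objective)
}

#' IFS curve plot
#'
#' Jackknife accuracy (or the chosen objective) against prefix size, with
#' the selected optimum marked.
#'
#' @param object An `ifs_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ifs_result <- function(object, ...) {
  df <- object$per_k
  obj <- object$objective
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data[[obj]])) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_vline(xintercept = object$optimal_k, linetype = "dashed") +
    ggplot2::labs(x = "number of ranked features in prefix",
                  y = paste("jackknife", obj),
                  title = sprintf("IFS curve (optimum k = %d, %s = %.3f)",
                                  object$optimal_k,
                                  obj, object$optimal_metrics[[obj]])) +
    ggplot2::theme_minimal()
}

#' Write / read the IFS curve table
#'
#' TSV with columns `k`, `Sn`, `Sp`, `AC`, `MCC` (the supplementary
#' per-predictor performance layout).
#'
#' @param ifs An `ifs_result`.
#' @param path TSV path.
#' @export
write_ifs_curve <- function(ifs, path) {
  readr::write_tsv(ifs$per_k[, c("k", "Sn", "Sp", "AC", "MCC")], path)
  invisible(path)
}

#' @rdname write_ifs_curve
#' @export
read_ifs_curve <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    k = readr::col_integer(), .default = readr::col_double()))
}
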