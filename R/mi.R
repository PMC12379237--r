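#' Mutual information between one feature and a binary label
#'
#' Direct empirical estimator: the feature is discretized into at most
#' `n_bins` equal-frequency bins (bins collapse when the feature has few
#' distinct values) and I(X;Y) is evaluated over the empirical joint
#' distribution with natural logarithms, with the usual convention
#' 0 * log 0 = 0. Scores are in nats and always non-negative; because
#' binning is by quantiles, the score is invariant under strictly monotone
#' transforms of the feature (up to tie effects).
#'
#' @param x Numeric feature vector.
#' @param y Binary label vector (0/1 or `"positive"`/`"negative"`), same
#'   length; both classes must be present.
#' @param n_bins Maximum number of feature bins (default 20).
#' @return Mutual information in nats.
#' @export
mi_score <- function(x, y, n_bins = 20) {
  y <- normalize_labels(y)
  stopifnot(length(x) == length(y))
  if (length(unique(y)) < 2L) stop("both classes must be present")
  bx <- bin_equal_frequency(x, n_bins)
  joint <- table(bx, y) / length(x)
  px <- rowSums(joint)
  py <- colSums(joint)
  terms <- joint * log(joint / outer(px, py))
  terms[joint == 0] <- 0
  max(0, sum(terms))
}

# Equal-frequency binning with distinct-value collapse: breakpoints are the
# unique quantiles, so features with <= n_bins distinct values keep one bin
# per value.
bin_equal_frequency <- function(x, n_bins) {
  br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1),
                               names = FALSE, type = 7))
  if (length(br) < 2L) return(rep(1L, length(x)))  # constant feature
  .bincode(x, br, right = TRUE, include.lowest = TRUE)
}

#' Rank features by mutual information and select the top k
#'
#' Scores every column of a feature matrix against the binary label, ranks
#' deterministically (score descending, column index ascending on ties) and
#' retains the first `k` columns. The per-category composition of the
#' retained set is reported alongside.
#'
#' @param features A `khib_features` object with labels, or a numeric matrix
#'   (then `labels` must be given).
#' @param k Number of features to keep (default 700). If `k` exceeds the
#'   column count a warning is issued and all columns are kept.
#' @param n_bins Bin count for [mi_score()].
#' @param labels Labels when `features` is a bare matrix.
#' @return An object of class `khib_selection`: list with `scores`,
#'   `ranking`, `selected` (column indices), `selected_names`, `k`,
#'   `category_counts`.
#' @export
rank_and_select <- function(features, k = 700, n_bins = 20, labels = NULL) {
  if (inherits(features, "khib_features")) {
    x <- features$x
    labels <- features$labels
    categories <- features$categories
  } else {
    x <- features
    categories <- factor(rep("all", ncol(x)))
  }
  if (is.null(labels)) stop("labels required for selection")
  y <- normalize_labels(labels)
  stopifnot(k >= 1)
  scores <- vapply(seq_len(ncol(x)), function(j) mi_score(x[, j], y, n_bins),
                   numeric(1))
  ranking <- order(-scores, seq_along(scores))
  if (k > ncol(x)) {
    warning(sprintf("k = %d exceeds %d columns; selecting all", k, ncol(x)))
    k <- ncol(x)
  }
  selected <- ranking[seq_len(k)]
  counts <- table(factor(categories[selected], levels = levels(categories)))
  structure(list(scores = scores, ranking = ranking, selected = selected,
                 selected_names = colnames(x)[selected], k = k,
                 category_counts = as.integer(counts),
                 categories = stats::setNames(as.integer(counts), names(counts))),
            class = "khib_selection")
}

#' Per-category composition of a selected feature set
#'
#' Percentage of the retained features contributed by each category
#' (embeddings, CTD, AAindex), rounded to 2 decimals.
#'
#' @param result A `khib_selection` from [rank_and_select()], or a named
#'   integer vector of per-category counts.
#' @return Named numeric vector of percentages summing to ~100.
#' @export
category_report <- function(result) {
  counts <- if (inherits(result, "khib_selection")) result$categories else result
  stopifnot(!is.null(names(counts)), all(counts >= 0))
  round(100 * counts / sum(counts), 2)
}

#' Write a selection result as JSON
#'
#' @param result A `khib_selection`.
#' @param path Output file.
#' @export
write_selection_json <- function(result, path) {
  jsonlite::write_json(
    list(scores = result$scores, ranking = result$ranking,
         selected_names = result$selected_names,
         category_percent = as.list(category_report(result))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
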