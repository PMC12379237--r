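#' Internal cluster-quality indices for class separation
#'
#' Quantifies how well a 1-D score vector or low-dimensional point set
#' separates the two classes: the mean silhouette width (Euclidean; higher
#' is better, range -1..1) and the Davies-Bouldin index (mean over clusters
#' of the worst-case (s_i + s_j) / M_ij ratio of centroid scatters to
#' centroid distance; lower is better). Typical inputs are classifier
#' probabilities or 2-D embedding coordinates.
#'
#' @param values Numeric vector (1-D) or matrix (samples x dims).
#' @param labels Binary class labels, at least 2 samples per class.
#' @return A list with `silhouette` and `davies_bouldin`.
#' @export
cluster_quality <- function(values, labels) {
  y <- normalize_labels(labels)
  x <- if (is.matrix(values)) values else matrix(values, ncol = 1)
  stopifnot(nrow(x) == length(y))
  if (min(tabulate(y + 1L, 2L)) < 2L) stop("need at least 2 samples per class")
  if (all(apply(x, 2, function(col) length(unique(col)) == 1L))) {
    stop("degenerate input: all points identical")
  }
  d <- as.matrix(stats::dist(x))
  sil <- numeric(length(y))
  for (i in seq_along(y)) {
    own <- y == y[i]
    a <- sum(d[i, own]) / (sum(own) - 1)      # mean distance to own cluster
    b <- mean(d[i, !own])
    sil[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  centroids <- rbind(colMeans(x[y == 0, , drop = FALSE]),
                     colMeans(x[y == 1, , drop = FALSE]))
  scatter <- c(mean(sqrt(rowSums((x[y == 0, , drop = FALSE] -
                                    matrix(centroids[1, ], sum(y == 0), ncol(x),
                                           byrow = TRUE))^2))),
               mean(sqrt(rowSums((x[y == 1, , drop = FALSE] -
                                    matrix(centroids[2, ], sum(y == 1), ncol(x),
                                           byrow = TRUE))^2))))
  M <- sqrt(sum((centroids[1, ] - centroids[2, ])^2))
  dbi <- if (M == 0) Inf else (scatter[1] + scatter[2]) / M
  list(silhouette = mean(sil), davies_bouldin = dbi)
}
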