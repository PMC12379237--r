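#' Pairwise identity of two padded windows
#'
#' Identity is the number of positions where both windows carry the same
#' non-padding residue, divided by the number of positions where at least one
#' window carries a non-padding residue. Padding (`"X"`) never counts as a
#' match. The function is symmetric and returns 1 for identical pad-free
#' windows.
#'
#' @param a,b Window strings of equal length.
#' @return Identity fraction in \[0, 1\].
#' @export
window_identity <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("windows have different lengths")
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  cover <- ca != PAD | cb != PAD
  if (!any(cover)) return(0)
  sum(ca == cb & ca != PAD & cb != PAD) / sum(cover)
}

#' Greedy incremental identity clustering
#'
#' Emulates CD-HIT-style redundancy removal: windows are processed in
#' canonical order (sorted by sequence, then accession, then position, so the
#' result does not depend on input order); each window joins the first
#' existing cluster whose representative shares identity strictly greater
#' than `identity_threshold`, otherwise it founds a new cluster and becomes
#' its representative.
#'
#' @param windows A `khib_windows` data frame or character vector of
#'   equal-length window strings.
#' @param identity_threshold Fraction in (0, 1\]; default 0.4, the
#'   conventional redundancy threshold for PTM datasets.
#' @param canonicalize Sort windows into canonical order before clustering
#'   (default `TRUE`). Set `FALSE` to cluster in input order.
#' @return A list of class `khib_clusters` with elements `clusters` (list of
#'   integer vectors of input indices), `representatives` (one input index
#'   per cluster) and `identity_threshold`.
#' @export
greedy_cluster <- function(windows, identity_threshold = 0.4, canonicalize = TRUE) {
  if (inherits(windows, "khib_windows")) {
    seqs <- windows$window
    ord_keys <- list(seqs, windows$accession, windows$position)
  } else {
    seqs <- as.character(windows)
    ord_keys <- list(seqs, seq_along(seqs))
  }
  if (length(seqs) == 0L) {
    return(structure(list(clusters = list(), representatives = integer(),
                          identity_threshold = identity_threshold),
                     class = "khib_clusters"))
  }
  if (length(unique(nchar(seqs))) != 1L) stop("windows have mixed lengths")
  stopifnot(identity_threshold > 0, identity_threshold <= 1)

  ord <- if (canonicalize) do.call(order, ord_keys) else seq_along(seqs)

  # character matrix once; reps compared against candidates by column scans
  chars <- do.call(rbind, strsplit(seqs, ""))
  reps <- integer(0)            # input indices of representatives
  members <- list()
  for (i in ord) {
    placed <- FALSE
    for (ci in seq_along(reps)) {
      r <- chars[reps[ci], ]
      w <- chars[i, ]
      cover <- sum(r != PAD | w != PAD)
      if (cover == 0) next
      ident <- sum(r == w & r != PAD) / cover
      if (ident > identity_threshold) {
        members[[ci]] <- c(members[[ci]], i)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, i)
      members[[length(reps)]] <- i
    }
  }
  structure(list(clusters = members, representatives = reps,
                 identity_threshold = identity_threshold),
            class = "khib_clusters")
}

#' Balance classes by cluster representatives and split the data
#'
#' Takes one representative window per positive cluster, draws (without
#' replacement, seeded) an equal number of negative cluster representatives,
#' and partitions the balanced set into a stratified train/test split with a
#' stratified fold assignment on the training part. Fully reproducible given
#' the seed.
#'
#' @param pos_windows,neg_windows `khib_windows` data frames.
#' @param pos_clusters,neg_clusters `khib_clusters` for the two sets; computed
#'   with [greedy_cluster()] at threshold 0.4 when `NULL`.
#' @param test_fraction Held-out fraction (default 0.1).
#' @param n_folds Number of cross-validation folds on the training part
#'   (default 10).
#' @param seed Integer seed controlling negative sampling, split and folds.
#' @return A list with `windows` (the balanced `khib_windows`, positives
#'   first), `train_indices`, `test_indices`, `fold_assignments` (fold id per
#'   training sample, parallel to `train_indices`) and `seed`.
#' @export
balance_and_split <- function(pos_windows, neg_windows,
                              pos_clusters = NULL, neg_clusters = NULL,
                              test_fraction = 0.1, n_folds = 10, seed = 42) {
  if (is.null(pos_clusters)) pos_clusters <- greedy_cluster(pos_windows)
  if (is.null(neg_clusters)) neg_clusters <- greedy_cluster(neg_windows)
  np <- length(pos_clusters$representatives)
  nn <- length(neg_clusters$representatives)
  if (nn < np) {
    stop(sprintf("insufficient negative clusters: %d negative vs %d positive", nn, np))
  }
  set.seed(seed)
  pos_sel <- pos_clusters$representatives
  neg_sel <- sort(sample(neg_clusters$representatives, np, replace = FALSE))
  sel <- rbind(as.data.frame(pos_windows)[pos_sel, , drop = FALSE],
               as.data.frame(neg_windows)[neg_sel, , drop = FALSE])
  rownames(sel) <- NULL
  win <- khib_windows(sel$window, sel$label, sel$accession, sel$position)

  sp <- stratified_split(win$label, test_fraction, n_folds, seed = seed + 1L)
  c(list(windows = win), sp, list(seed = seed))
}

# Stratified test split + stratified fold assignment. Per class the test set
# takes round(test_fraction * n); remaining samples are shuffled and dealt
# round-robin into folds so per-fold class counts differ by at most 1.
stratified_split <- function(labels, test_fraction = 0.1, n_folds = 10, seed = 42) {
  set.seed(seed)
  test <- integer(0)
  train <- integer(0)
  folds <- integer(0)
  for (cl in sort(unique(labels))) {
    idx <- which(labels == cl)
    idx <- sample(idx)
    n_test <- round(test_fraction * length(idx))
    test <- c(test, idx[seq_len(n_test)])
    tr <- idx[setdiff(seq_along(idx), seq_len(n_test))]
    train <- c(train, tr)
    folds <- c(folds, rep_len(seq_len(n_folds), length(tr)))
  }
  o <- order(train)
  list(train_indices = train[o], test_indices = sort(test),
       fold_assignments = folds[o])
}
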