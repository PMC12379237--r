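#' Assemble category-tagged feature blocks into one matrix
#'
#' Column-binds per-category feature blocks (same samples, same row order)
#' into a single matrix whose column names are prefixed with the category
#' (`esm.`, `ctd.`, `aaidx.`), keeping a per-column category tag for the
#' selection report. With the default configuration (480-dim embeddings,
#' 147 CTD features, 20 scales x 43 positions AAindex) the matrix has
#' 1487 columns.
#'
#' @param blocks Named list of numeric matrices with equal row counts; names
#'   are the category tags, conventionally `esm`, `ctd`, `aaidx` in that
#'   order.
#' @param labels Optional vector of sample labels (`"positive"` /
#'   `"negative"` or 0/1).
#' @param sample_ids Optional sample identifiers.
#' @return An object of class `khib_features`: a list with `x` (matrix),
#'   `labels`, `categories` (factor per column) and `sample_ids`.
#' @export
assemble_features <- function(blocks, labels = NULL, sample_ids = NULL) {
  stopifnot(is.list(blocks), length(blocks) >= 1, !is.null(names(blocks)))
  nr <- vapply(blocks, nrow, integer(1))
  if (length(unique(nr)) != 1L) {
    stop("blocks cover different sample counts: ",
         paste(paste0(names(blocks), "=", nr), collapse = ", "))
  }
  for (nm in names(blocks)) {
    colnames(blocks[[nm]]) <- paste0(nm, ".", colnames(blocks[[nm]]))
  }
  x <- do.call(cbind, blocks)
  if (anyNA(x) || any(!is.finite(x))) stop("feature matrix contains missing values")
  categories <- factor(rep(names(blocks), vapply(blocks, ncol, integer(1))),
                       levels = names(blocks))
  if (!is.null(labels)) {
    labels <- normalize_labels(labels)
    stopifnot(length(labels) == nrow(x))
  }
  if (is.null(sample_ids)) sample_ids <- seq_len(nrow(x))
  structure(list(x = x, labels = labels, categories = categories,
                 sample_ids = sample_ids),
            class = "khib_features")
}

# Accepts "positive"/"negative", logical, or 0/1; returns integer 0/1.
normalize_labels <- function(labels) {
  if (is.character(labels) || is.factor(labels)) {
    labels <- as.character(labels)
    if (!all(labels %in% c("positive", "negative"))) {
      stop("labels must be 'positive'/'negative' or 0/1")
    }
    return(as.integer(labels == "positive"))
  }
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 'positive'/'negative' or 0/1")
  labels
}

#' Build the full hybrid feature matrix for a window set
#'
#' Convenience wrapper running the configured encoders and assembling their
#' blocks: embeddings (`esm`), CTD descriptors (`ctd`) and position-specific
#' AAindex values (`aaidx`).
#'
#' @param windows A `khib_windows` data frame (labels are carried over) or a
#'   character vector of window strings.
#' @param blocks Character vector naming the blocks to build, a subset of
#'   `c("esm", "ctd", "aaidx")`, in output order.
#' @param provider Embedding provider for the `esm` block.
#' @param groupings CTD attribute groupings.
#' @param table AAindex property table.
#' @return A `khib_features` object.
#' @export
build_feature_matrix <- function(windows, blocks = c("esm", "ctd", "aaidx"),
                                 provider = offline_provider(),
                                 groupings = ctd_groupings(),
                                 table = default_aaindex()) {
  blocks <- match.arg(blocks, c("esm", "ctd", "aaidx"), several.ok = TRUE)
  labels <- if (inherits(windows, "khib_windows")) windows$label else NULL
  if (!is.null(labels) && any(labels == "unknown")) labels <- NULL
  w <- if (inherits(windows, "khib_windows")) windows$window else as.character(windows)
  built <- list()
  for (b in blocks) {
    built[[b]] <- switch(b,
      esm = embed_windows(w, provider),
      ctd = ctd_encode(w, groupings),
      aaidx = aaindex_encode(w, table))
  }
  assemble_features(built, labels = labels)
}
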