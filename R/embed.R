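# Cache of deterministic token vectors, keyed by "<dim>:<token>".
.token_cache <- new.env(parent = emptyenv())

# Deterministic 31-bit hash of a token string (polynomial rolling hash; all
# intermediates stay below 2^53 so double arithmetic is exact).
token_hash <- function(token) {
  h <- 0
  for (code in utf8ToInt(token)) h <- (h * 131 + code) %% 2147483629
  as.integer(h)
}

# Deterministic pseudo-random vector for a token: seed the RNG from the token
# hash, draw `dim` standard normals, and restore the caller's RNG state.
token_vector <- function(token, dim) {
  key <- paste0(dim, ":", token)
  v <- .token_cache[[key]]
  if (!is.null(v)) return(v)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(token_hash(token))
  v <- stats::rnorm(dim)
  .token_cache[[key]] <- v
  v
}

#' Offline deterministic residue-embedding provider
#'
#' A self-contained embedding provider that assigns every residue a
#' deterministic vector derived by hashing the residue identity and its
#' position-independent context k-mer into the declared dimension. It stands
#' behind the same adapter contract as an external protein language model
#' (fixed output dimension, per-residue vectors, mean pooling), so the rest
#' of the pipeline is agnostic to where embeddings come from, and it needs no
#' downloads or network access.
#'
#' @param dim Output dimension (default 480, the width of the mid-size
#'   protein-language-model embeddings the pipeline is designed around).
#' @param k Context k-mer length (odd, default 3).
#' @return An object of class `embedding_provider` with elements `dim`,
#'   `name` and `encode(windows)`.
#' @export
offline_provider <- function(dim = 480, k = 3) {
  stopifnot(dim >= 1, k >= 1, k %% 2 == 1)
  encode <- function(windows) {
    chars <- do.call(rbind, strsplit(windows, ""))
    n <- nrow(chars)
    L <- ncol(chars)
    half <- (k - 1L) %/% 2L
    padded <- cbind(matrix(PAD, n, half), chars, matrix(PAD, n, half))
    # token per (window, position): residue letter and centred k-mer
    kmers <- matrix("", n, L)
    for (p in seq_len(L)) {
      block <- padded[, p:(p + k - 1L), drop = FALSE]
      kmers[, p] <- do.call(paste0, as.data.frame(block, stringsAsFactors = FALSE))
    }
    keep <- chars != PAD            # padding positions are excluded from pooling
    if (any(rowSums(keep) == 0)) stop("window with no non-padding residues")
    tokens <- c(paste0("r:", chars[keep]), paste0("m:", kmers[keep]))
    win_id <- rep(row(chars)[keep], 2L)
    utok <- unique(tokens)
    M <- do.call(rbind, lapply(utok, token_vector, dim = dim))
    # counts: windows x tokens (sparse), pooled mean over non-pad positions
    C <- Matrix::sparseMatrix(i = win_id, j = match(tokens, utok),
                              x = 1, dims = c(n, length(utok)))
    pooled <- as.matrix(C %*% M) / rowSums(keep)
    rownames(pooled) <- NULL
    pooled
  }
  structure(list(dim = as.integer(dim), k = as.integer(k),
                 name = sprintf("offline-hash-%dd", dim), encode = encode),
            class = "embedding_provider")
}

#' Wrap an external per-residue embedder as a provider
#'
#' Adapter contract for plugging in any external residue-level embedder
#' (e.g. a transformer protein language model run out-of-band): supply a
#' function that maps a character vector of windows to a numeric matrix of
#' per-window vectors of fixed width `dim` (the adapter performs no pooling;
#' the supplied function is expected to return already-pooled vectors, or may
#' itself call [pool_residue_vectors()]).
#'
#' @param encode Function `character -> matrix` with `dim` columns.
#' @param dim Declared output dimension.
#' @param name Provider label.
#' @return An `embedding_provider`.
#' @export
embedding_adapter <- function(encode, dim, name = "external") {
  stopifnot(is.function(encode), dim >= 1)
  structure(list(dim = as.integer(dim), name = name, encode = encode),
            class = "embedding_provider")
}

#' Mean-pool per-residue vectors into one window vector
#'
#' @param residue_vectors Numeric matrix, one row per residue position.
#' @param is_pad Logical vector flagging padding positions (excluded).
#' @return A numeric vector (column means over non-padding rows).
#' @export
pool_residue_vectors <- function(residue_vectors, is_pad = rep(FALSE, nrow(residue_vectors))) {
  keep <- !is_pad
  if (!any(keep)) stop("no non-padding residues to pool")
  colMeans(residue_vectors[keep, , drop = FALSE])
}

#' Embed peptide windows with a provider
#'
#' One vector per window: the mean over the provider's residue-level vectors,
#' with padding positions excluded. Deterministic for the offline provider.
#'
#' @param windows Character vector of window strings or a `khib_windows`
#'   data frame.
#' @param provider An `embedding_provider` (default [offline_provider()]).
#' @return Numeric matrix (windows x `provider$dim`) with columns
#'   `e1..e<dim>`.
#' @export
embed_windows <- function(windows, provider = offline_provider()) {
  if (inherits(windows, "khib_windows")) windows <- windows$window
  stopifnot(inherits(provider, "embedding_provider"))
  m <- provider$encode(as.character(windows))
  if (ncol(m) != provider$dim) {
    stop(sprintf("provider returned %d dimensions, declared %d",
                 ncol(m), provider$dim))
  }
  colnames(m) <- paste0("e", seq_len(ncol(m)))
  m
}
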