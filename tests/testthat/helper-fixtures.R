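# Shared fixtures built in code.

# The 20-residue hand-worked example sequence used for CTD descriptors.
EXAMPLE20 <- "AFDQFGHIKLMEPRQTSIWS"

# A deterministic random protein with a known lysine layout.
random_protein <- function(n, seed = 1, alphabet = khibkit:::AA20) {
  set.seed(seed)
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Random fixed-length windows over the 20 letters (no padding).
random_windows <- function(n, len = 43, seed = 1) {
  set.seed(seed)
  vapply(seq_len(n), function(i) {
    paste(sample(khibkit:::AA20, len, replace = TRUE), collapse = "")
  }, character(1))
}

# Two well-separated Gaussian blobs as a khib_features object.
blob_features <- function(n_per_class = 50, p = 5, sep = 6, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per_class * p), ncol = p),
             matrix(rnorm(n_per_class * p, mean = sep), ncol = p))
  colnames(x) <- paste0("f", seq_len(p))
  assemble_features(list(all = x),
                    labels = rep(c(0L, 1L), each = n_per_class))
}

# Fast booster settings for unit tests (the tuned defaults are exercised in
# the end-to-end acceptance suite).
fast_params <- function(...) booster_params(n_estimators = 40, ...)
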