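#' Run the full prediction pipeline on a labelled window set
#'
#' Hybrid encoding (embeddings + CTD + AAindex), per-fold mutual-information
#' selection of the top `k` features, and stratified cross-validation of the
#' boosted-tree classifier. This is the end-to-end path a user runs on their
#' own site table, and the path the synthetic presets are designed to
#' exercise offline.
#'
#' @param windows A labelled `khib_windows` data frame.
#' @param k Number of MI-selected features per fold (default 700;
#'   `NULL` disables selection).
#' @param params Booster configuration (default [booster_params()]).
#' @param n_folds Cross-validation folds (default 10).
#' @param seed Integer seed.
#' @param blocks Feature blocks to build.
#' @param provider Embedding provider.
#' @param nthread Engine threads.
#' @return A list with `cv` (the [cross_validate()] result), `features_dim`
#'   (columns of the assembled matrix) and `n` (sample count).
#' @export
run_khib_pipeline <- function(windows, k = 700, params = booster_params(),
                              n_folds = 10, seed = 42,
                              blocks = c("esm", "ctd", "aaidx"),
                              provider = offline_provider(), nthread = 1) {
  feats <- build_feature_matrix(windows, blocks = blocks, provider = provider)
  cv <- cross_validate(feats, params, n_folds = n_folds, seed = seed,
                       select_k = k, nthread = nthread)
  list(cv = cv, features_dim = ncol(feats$x), n = nrow(feats$x))
}
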