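#' Gradient-boosted tree hyperparameters
#'
#' Parameter contract for the boosted-tree engine. Defaults are the tuned
#' operating point for Khib site prediction on hybrid features: 500 trees,
#' learning rate 0.1, maximum depth 11, 89 leaves, L1 = 1.15e-5,
#' L2 = 4.4e-8; `colsample_bytree`, `subsample` and `min_child_samples`
#' keep their engine defaults. `max_depth = -1` means unlimited depth.
#'
#' @param n_estimators Number of boosting rounds.
#' @param learning_rate Shrinkage per round.
#' @param max_depth Maximum tree depth (-1 = unlimited).
#' @param num_leaves Maximum leaves per tree (leaf-wise growth).
#' @param colsample_bytree Feature subsampling fraction per tree.
#' @param subsample Row subsampling fraction per tree.
#' @param min_child_samples Minimum samples per leaf (`NULL` = engine
#'   default; mapped to the engine's minimum-child-weight control).
#' @param l1,l2 L1 / L2 regularization strengths.
#' @return A list of class `booster_params`.
#' @export
booster_params <- function(n_estimators = 500, learning_rate = 0.1,
                           max_depth = 11, num_leaves = 89,
                           colsample_bytree = 1, subsample = 1,
                           min_child_samples = NULL,
                           l1 = 1.15e-5, l2 = 4.4e-8) {
  stopifnot(n_estimators >= 1, learning_rate > 0,
            max_depth == -1 || max_depth >= 1, num_leaves >= 2,
            colsample_bytree > 0, colsample_bytree <= 1,
            subsample > 0, subsample <= 1, l1 >= 0, l2 >= 0)
  structure(list(n_estimators = as.integer(n_estimators),
                 learning_rate = learning_rate,
                 max_depth = as.integer(max_depth),
                 num_leaves = as.integer(num_leaves),
                 colsample_bytree = colsample_bytree,
                 subsample = subsample,
                 min_child_samples = min_child_samples,
                 l1 = l1, l2 = l2),
            class = "booster_params")
}

# Tested search ranges for each tunable parameter.
booster_search_space <- function() {
  list(n_estimators = c(100, 1000), learning_rate = c(0.01, 0.1),
       max_depth = c(-1, 12), num_leaves = c(31, 150),
       colsample_bytree = c(0.5, 1), subsample = c(0.5, 1),
       min_child_samples = c(5, 100), l1 = c(1e-8, 10), l2 = c(1e-8, 10))
}

# Translate the contract into engine parameters. Leaf-wise (best-first)
# growth with histogram binning; single-threaded for bit-reproducibility.
engine_params <- function(params, seed, nthread = 1) {
  p <- list(objective = "binary:logistic",
            tree_method = "hist", grow_policy = "lossguide",
            learning_rate = params$learning_rate,
            max_depth = if (params$max_depth == -1L) 0L else params$max_depth,
            max_leaves = params$num_leaves,
            colsample_bytree = params$colsample_bytree,
            subsample = params$subsample,
            reg_alpha = params$l1, reg_lambda = params$l2,
            nthread = nthread, seed = seed)
  if (!is.null(params$min_child_samples)) {
    # the engine's minimum-child control is a hessian sum; for logistic loss
    # each sample contributes at most 1/4, so scale the sample count by 0.25
    p$min_child_weight <- 0.25 * params$min_child_samples
  }
  do.call(xgboost::xgb.params, p)
}

#' Train the boosted-tree classifier
#'
#' Fits a binary classifier (cross-entropy loss) on a feature matrix and
#' returns a model bundle carrying the fitted booster, the parameters, the
#' ordered feature manifest and the seed, so predictions are reproducible
#' and column alignment is by name rather than position.
#'
#' @param features A `khib_features` object with labels, or a numeric matrix
#'   with column names (then `labels` is required).
#' @param params A [booster_params()] configuration.
#' @param seed Integer seed (single-threaded training is then
#'   bit-reproducible on one platform).
#' @param selection Optional `khib_selection`; when given, training is
#'   restricted to the selected columns.
#' @param labels Labels when `features` is a bare matrix.
#' @param nthread Engine threads (default 1 for determinism).
#' @return An object of class `khib_model`.
#' @export
train_booster <- function(features, params = booster_params(), seed = 42,
                          selection = NULL, labels = NULL, nthread = 1) {
  if (inherits(features, "khib_features")) {
    x <- features$x
    labels <- features$labels
  } else {
    x <- features
  }
  y <- normalize_labels(labels)
  if (length(unique(y)) < 2L || min(tabulate(y + 1L, 2L)) < 2L) {
    stop("need at least 2 samples per class")
  }
  if (!is.null(selection)) x <- x[, selection$selected, drop = FALSE]
  bad <- which(!apply(is.finite(x), 2, all))
  if (length(bad)) {
    stop("non-finite values in feature column(s): ",
         paste(utils::head(colnames(x)[bad], 10), collapse = ", "))
  }
  dtrain <- xgboost::xgb.DMatrix(x, label = y, nthread = nthread)
  booster <- xgboost::xgb.train(params = engine_params(params, seed, nthread),
                                data = dtrain,
                                nrounds = params$n_estimators, verbose = 0)
  structure(list(booster = booster, params = params,
                 feature_names = colnames(x), seed = seed,
                 n_train = nrow(x)),
            class = "khib_model")
}

#' Predict positive-class probabilities
#'
#' Columns of the input are aligned to the model's feature manifest by name,
#' so any column order (or a superset of columns) gives identical scores.
#'
#' @param model A `khib_model` from [train_booster()].
#' @param features A `khib_features` object or numeric matrix with column
#'   names covering the manifest.
#' @return Numeric vector of probabilities in \[0, 1\].
#' @export
predict_scores <- function(model, features) {
  x <- if (inherits(features, "khib_features")) features$x else features
  missing <- setdiff(model$feature_names, colnames(x))
  if (length(missing)) {
    stop("feature column(s) missing from input: ",
         paste(utils::head(missing, 10), collapse = ", "))
  }
  x <- x[, model$feature_names, drop = FALSE]
  as.numeric(predict(model$booster, x))
}

#' Stratified k-fold cross-validation
#'
#' Fits on k-1 folds and evaluates on the held-out fold, optionally running
#' mutual-information selection inside each training fold (so feature
#' selection never sees validation data). Fold assignment is stratified and
#' seeded.
#'
#' @param features A `khib_features` object with labels.
#' @param params A [booster_params()] configuration.
#' @param n_folds Number of folds (default 10).
#' @param seed Integer seed for folds and training.
#' @param select_k When non-`NULL`, the per-fold number of MI-selected
#'   features (e.g. 700).
#' @param n_bins MI bin count.
#' @param threshold Score threshold for confusion metrics.
#' @param nthread Engine threads.
#' @return A list with `per_fold` (data frame of metrics per fold), `mean`
#'   and `sd` (named metric vectors) and `fold_assignments`.
#' @export
cross_validate <- function(features, params = booster_params(), n_folds = 10,
                           seed = 42, select_k = NULL, n_bins = 20,
                           threshold = 0.5, nthread = 1) {
  y <- normalize_labels(features$labels)
  # test_fraction 0 keeps every sample; only the fold assignment is used
  ord <- stratified_split(y, 0, n_folds, seed = seed)
  fold_of <- integer(length(y))
  fold_of[ord$train_indices] <- ord$fold_assignments
  rows <- list()
  for (f in seq_len(n_folds)) {
    tr <- which(fold_of != f)
    va <- which(fold_of == f)
    if (length(unique(y[va])) < 2L) stop("fold ", f, " holds a single class")
    sub <- structure(list(x = features$x[tr, , drop = FALSE], labels = y[tr],
                          categories = features$categories),
                     class = "khib_features")
    sel <- if (!is.null(select_k)) rank_and_select(sub, k = select_k, n_bins = n_bins)
    model <- train_booster(sub, params, seed = seed + f, selection = sel,
                           nthread = nthread)
    sc <- predict_scores(model, features$x[va, , drop = FALSE])
    cm <- confusion_metrics(y[va], sc, threshold)
    auc <- roc_auc(y[va], sc)$auc
    rows[[f]] <- data.frame(fold = f, n = length(va), ACC = cm$ACC, SN = cm$SN,
                            SP = cm$SP, PR = cm$PR, F1 = cm$F1, MCC = cm$MCC,
                            AUC = auc)
  }
  per_fold <- do.call(rbind, rows)
  metric_cols <- c("ACC", "SN", "SP", "PR", "F1", "MCC", "AUC")
  list(per_fold = per_fold,
       mean = colMeans(per_fold[metric_cols]),
       sd = vapply(per_fold[metric_cols], stats::sd, numeric(1)),
       fold_assignments = fold_of)
}

#' Seeded random-search hyperparameter tuning
#'
#' Draws `n_trials` configurations uniformly from the tested ranges
#' (log-uniform for the regularization strengths) and returns the
#' configuration maximizing mean cross-validated AUC, together with the full
#' trial log.
#'
#' @inheritParams cross_validate
#' @param n_trials Number of sampled configurations (default 100).
#' @return List with `best_params`, `best_auc` and `trials` (data frame).
#' @export
tune_booster <- function(features, n_trials = 100, n_folds = 10, seed = 42,
                         select_k = NULL, nthread = 1) {
  stopifnot(n_trials >= 1)
  space <- booster_search_space()
  set.seed(seed)
  draws <- lapply(seq_len(n_trials), function(i) {
    md <- sample(c(-1L, seq.int(1L, space$max_depth[2])), 1L)
    booster_params(
      n_estimators = sample(space$n_estimators[1]:space$n_estimators[2], 1L),
      learning_rate = stats::runif(1, space$learning_rate[1], space$learning_rate[2]),
      max_depth = md,
      num_leaves = sample(space$num_leaves[1]:space$num_leaves[2], 1L),
      colsample_bytree = stats::runif(1, space$colsample_bytree[1], space$colsample_bytree[2]),
      subsample = stats::runif(1, space$subsample[1], space$subsample[2]),
      min_child_samples = sample(space$min_child_samples[1]:space$min_child_samples[2], 1L),
      l1 = exp(stats::runif(1, log(space$l1[1]), log(space$l1[2]))),
      l2 = exp(stats::runif(1, log(space$l2[1]), log(space$l2[2]))))
  })
  aucs <- vapply(seq_along(draws), function(i) {
    cross_validate(features, draws[[i]], n_folds = n_folds, seed = seed,
                   select_k = select_k, nthread = nthread)$mean[["AUC"]]
  }, numeric(1))
  trials <- cbind(trial = seq_len(n_trials),
                  do.call(rbind, lapply(draws, function(p) {
                    as.data.frame(lapply(p, function(v) if (is.null(v)) NA else v))
                  })),
                  cv_auc = aucs)
  best <- which.max(aucs)
  list(best_params = draws[[best]], best_auc = aucs[best], trials = trials)
}

#' Scan peptide window sizes
#'
#' Re-runs the pipeline (window extraction, encoding, optional MI selection,
#' stratified cross-validation) for each candidate window size and reports
#' the mean CV AUC per size. Sizes must be odd (a central lysine plus equal
#' flanks).
#'
#' @param prot Protein table.
#' @param sites Site table with positive and negative rows.
#' @param sizes Odd window lengths to evaluate (default 35, 37, ..., 47).
#' @param blocks Feature blocks to build (see [build_feature_matrix()]).
#' @inheritParams cross_validate
#' @param provider Embedding provider for the `esm` block.
#' @return Data frame with columns `size`, `flank`, `cv_auc`.
#' @export
window_size_scan <- function(prot, sites, sizes = seq(35, 47, by = 2),
                             blocks = c("esm", "ctd", "aaidx"),
                             params = booster_params(), n_folds = 10,
                             seed = 42, select_k = NULL,
                             provider = offline_provider(), nthread = 1) {
  if (any(sizes %% 2 == 0)) stop("window sizes must be odd")
  rows <- lapply(sizes, function(sz) {
    flank <- (sz - 1L) / 2L
    win <- build_windows(prot, sites, flank = flank)
    feats <- build_feature_matrix(win, blocks = blocks, provider = provider)
    cv <- cross_validate(feats, params, n_folds = n_folds, seed = seed,
                         select_k = select_k, nthread = nthread)
    data.frame(size = sz, flank = flank, cv_auc = cv$mean[["AUC"]])
  })
  do.call(rbind, rows)
}

#' Persist / restore a model bundle
#'
#' The booster is written in the engine's native format alongside a JSON
#' manifest (parameters, ordered feature names, seed).
#'
#' @param model A `khib_model`.
#' @param path Basename; writes `<path>.ubj` and `<path>.json`.
#' @export
save_model <- function(model, path) {
  xgboost::xgb.save(model$booster, paste0(path, ".ubj"))
  manifest <- list(params = model$params[!vapply(model$params, is.null, logical(1))],
                   feature_names = model$feature_names,
                   seed = model$seed, n_train = model$n_train)
  jsonlite::write_json(manifest, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @return `load_model()` returns the restored `khib_model`.
#' @export
load_model <- function(path) {
  booster <- xgboost::xgb.load(paste0(path, ".ubj"))
  man <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  params <- do.call(booster_params, as.list(man$params))
  structure(list(booster = booster, params = params,
                 feature_names = man$feature_names, seed = man$seed,
                 n_train = man$n_train),
            class = "khib_model")
}
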