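test_that("the booster separates well-separated blobs and is deterministic", {
  f <- blob_features(n_per_class = 40, sep = 6, seed = 25)
  m1 <- train_booster(f, fast_params(), seed = 7)
  m2 <- train_booster(f, fast_params(), seed = 7)
  s1 <- predict_scores(m1, f)
  s2 <- predict_scores(m2, f)
  expect_identical(s1, s2)
  expect_equal(roc_auc(f$labels, s1)$auc, 1)
  expect_true(all(s1[f$labels == 1] > 0.5) && all(s1[f$labels == 0] < 0.5))
})

test_that("prediction aligns columns by name, not position", {
  f <- blob_features(n_per_class = 30, seed = 26)
  m <- train_booster(f, fast_params(), seed = 1)
  x <- f$x
  shuffled <- x[, rev(colnames(x))]
  expect_equal(predict_scores(m, shuffled), predict_scores(m, x))

  dup <- x[c(1, 1, 2:nrow(x)), ]
  sc <- predict_scores(m, dup)
  expect_equal(sc[1], sc[2])

  expect_error(predict_scores(m, x[, -1]), "missing from input.*all.f1")
})

test_that("training validates inputs", {
  f <- blob_features(10, seed = 27)
  bad <- f
  bad$x[3, 2] <- NA
  expect_error(train_booster(bad, fast_params()), "non-finite.*all.f2")
  one_class <- f
  one_class$labels <- rep(1L, length(f$labels))
  expect_error(train_booster(one_class, fast_params()), "2 samples per class")
})

test_that("cross-validation is stratified and detects planted signal", {
  set.seed(28)
  n <- 1000
  y <- rep(c(0L, 1L), each = n / 2)
  x <- cbind(matrix(rnorm(n * 8), n), sig = y + rnorm(n, sd = 0.8))
  colnames(x) <- paste0("f", 1:9)
  f <- assemble_features(list(all = x), labels = y)
  cv <- cross_validate(f, fast_params(), n_folds = 10, seed = 3)
  expect_equal(nrow(cv$per_fold), 10)
  expect_true(all(cv$per_fold$n %in% 100))
  expect_gt(cv$mean[["AUC"]], 0.5 + 3 * cv$sd[["AUC"]] / sqrt(10))

  # validation folds hold 50 +- 1 samples per class
  tab <- table(cv$fold_assignments, f$labels)
  expect_true(all(abs(tab - 50) <= 1))
})

test_that("cross-validated AUC sits at chance for permuted labels", {
  set.seed(29)
  n <- 1000
  x <- matrix(rnorm(n * 10), n)
  colnames(x) <- paste0("f", 1:10)
  y <- sample(rep(c(0L, 1L), each = n / 2))     # labels independent of x
  f <- assemble_features(list(all = x), labels = y)
  cv <- cross_validate(f, fast_params(), n_folds = 10, seed = 4)
  expect_gt(cv$mean[["AUC"]], 0.45)
  expect_lt(cv$mean[["AUC"]], 0.55)
})

test_that("random-search tuning stays inside the tested ranges and does no harm", {
  f <- blob_features(n_per_class = 200, sep = 4, seed = 30)
  tuned <- tune_booster(f, n_trials = 5, n_folds = 3, seed = 9)
  space <- khibkit:::booster_search_space()
  for (tr in seq_len(nrow(tuned$trials))) {
    row <- tuned$trials[tr, ]
    expect_true(row$n_estimators >= 100 && row$n_estimators <= 1000)
    expect_true(row$learning_rate >= 0.01 && row$learning_rate <= 0.1)
    expect_true(row$max_depth %in% c(-1L, 1:12))
    expect_true(row$num_leaves >= 31 && row$num_leaves <= 150)
    expect_true(row$l1 >= 1e-8 && row$l1 <= 10)
    expect_true(row$l2 >= 1e-8 && row$l2 <= 10)
  }
  default_cv <- cross_validate(f, booster_params(n_estimators = 100),
                               n_folds = 3, seed = 9)
  expect_gte(tuned$best_auc, default_cv$mean[["AUC"]] - 0.02)

  single <- tune_booster(f, n_trials = 1, n_folds = 2, seed = 10)
  expect_equal(nrow(single$trials), 1)
  expect_s3_class(single$best_params, "booster_params")
  expect_error(tune_booster(f, n_trials = 0), "n_trials")
})

test_that("window-size scan runs the pipeline per size, deterministically", {
  cfg <- synthetic_config(30, 30, flank = 5, preset = "human", seed = 31)
  gp <- generate_proteome(cfg, n_proteins = 12, protein_length = 80,
                          sites_per_protein = 2)
  negs <- do.call(rbind, lapply(seq_len(nrow(gp$proteins)), function(i) {
    acc <- gp$proteins$accession[i]
    as.data.frame(enumerate_negative_windows(
      gp$proteins$sequence[i], gp$sites$position[gp$sites$accession == acc],
      flank = 5, accession = acc))
  }))
  n_neg <- min(nrow(gp$sites), nrow(negs))
  sites <- rbind(gp$sites,
                 data.frame(accession = negs$accession[seq_len(n_neg)],
                            position = negs$position[seq_len(n_neg)],
                            label = "negative"))
  scan <- window_size_scan(gp$proteins, sites, sizes = c(7, 9),
                           blocks = "ctd", params = fast_params(),
                           n_folds = 2, seed = 5)
  expect_equal(scan$size, c(7, 9))
  expect_true(all(scan$cv_auc >= 0 & scan$cv_auc <= 1))
  scan2 <- window_size_scan(gp$proteins, sites, sizes = c(7, 9),
                            blocks = "ctd", params = fast_params(),
                            n_folds = 2, seed = 5)
  expect_identical(scan, scan2)
  expect_error(window_size_scan(gp$proteins, sites, sizes = c(8)), "odd")
})

test_that("model bundles survive a save/load round-trip", {
  f <- blob_features(n_per_class = 20, seed = 32)
  m <- train_booster(f, fast_params(), seed = 2)
  path <- file.path(tempdir(), "khib-model")
  save_model(m, path)
  m2 <- load_model(path)
  expect_equal(predict_scores(m2, f), predict_scores(m, f))
  expect_identical(m2$feature_names, m$feature_names)
})
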