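test_that("confusion metrics reproduce the hand-evaluated oracle", {
  # TP=3, FN=1, TN=2, FP=2 encoded as labels/scores at threshold 0.5
  labels <- c(1, 1, 1, 1, 0, 0, 0, 0)
  scores <- c(0.9, 0.8, 0.7, 0.2, 0.6, 0.55, 0.3, 0.1)
  m <- confusion_metrics(labels, scores)
  expect_equal(c(m$TP, m$FN, m$TN, m$FP), c(3, 1, 2, 2))
  expect_equal(m$ACC, 0.625)
  expect_equal(m$SN, 0.75)
  expect_equal(m$SP, 0.5)
  expect_equal(m$PR, 0.6)
  expect_equal(m$F1, 2 * 0.6 * 0.75 / (0.6 + 0.75))
  expect_equal(m$MCC, (3 * 2 - 2 * 1) / sqrt(5 * 4 * 4 * 3))

  perfect <- confusion_metrics(labels, labels)
  expect_equal(unlist(perfect[c("ACC", "SN", "SP", "PR", "F1", "MCC")]),
               c(ACC = 1, SN = 1, SP = 1, PR = 1, F1 = 1, MCC = 1))

  all_pos <- confusion_metrics(c(1, 1, 0, 0), rep(1, 4))
  expect_equal(c(all_pos$SN, all_pos$SP, all_pos$ACC), c(1, 0, 0.5))
  # degenerate denominator convention
  expect_equal(all_pos$MCC, 0)
})

test_that("AUC equals brute-force pair counting with half credit for ties", {
  set.seed(19)
  for (rep_i in 1:5) {
    n <- 16
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    scores <- round(runif(n), 1)          # coarse grid forces ties
    pos <- scores[labels == 1]
    neg <- scores[labels == 0]
    wins <- 0
    for (p in pos) for (q in neg) wins <- wins + (p > q) + 0.5 * (p == q)
    expect_equal(roc_auc(labels, scores)$auc, wins / (length(pos) * length(neg)))
  }
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(20)
  labels <- rbinom(300, 1, 0.5)
  scores <- labels + rnorm(300)
  expect_equal(roc_auc(labels, scores)$auc,
               as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE))))
})

test_that("ROC curve is monotone from (0,0) to (1,1) and AUC is well-behaved", {
  set.seed(21)
  labels <- rbinom(500, 1, 0.5)
  scores <- labels * 0.8 + rnorm(500)
  r <- roc_auc(labels, scores)
  expect_equal(unlist(r$curve[1, c("fpr", "tpr")]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(r$curve[nrow(r$curve), c("fpr", "tpr")]), c(fpr = 1, tpr = 1))
  expect_true(all(diff(r$curve$fpr) >= 0) && all(diff(r$curve$tpr) >= 0))

  expect_equal(roc_auc(labels, labels)$auc, 1)
  # complement and monotone-transform invariances
  expect_equal(roc_auc(labels, -scores)$auc, 1 - r$auc)
  expect_equal(roc_auc(labels, exp(scores))$auc, r$auc)

  # chance level for independent scores
  expect_lt(abs(roc_auc(rbinom(2000, 1, 0.5), rnorm(2000))$auc - 0.5), 0.03)
})

test_that("Hanley-McNeil comparison behaves at its algebraic limits", {
  set.seed(22)
  labels <- rbinom(200, 1, 0.5)
  s <- labels + rnorm(200)
  same <- hanley_mcneil_compare(labels, s, s)
  expect_equal(same$z, 0)
  expect_equal(same$p, 1)

  s2 <- labels + rnorm(200)
  ab <- hanley_mcneil_compare(labels, s, s2)
  ba <- hanley_mcneil_compare(labels, s2, s)
  expect_equal(ab$z, -ba$z)                     # antisymmetry
  # z recomposes from the reported parts
  expect_equal(ab$z, (ab$auc_a - ab$auc_b) /
                 sqrt(ab$se_a^2 + ab$se_b^2 - 2 * ab$r * ab$se_a * ab$se_b))
  # with r = 0 and equal SEs s0 the denominator reduces to s0 * sqrt(2)
  expect_equal(sqrt(ab$se_a^2 + ab$se_a^2 - 0), ab$se_a * sqrt(2))
  expect_error(hanley_mcneil_compare(labels, s, s2[-1]), "same samples")
})

test_that("cluster quality indices match hand computation and limits", {
  vals <- c(0, 0.1, 0.9, 1.0)
  labs <- c(0, 0, 1, 1)
  q <- cluster_quality(vals, labs)
  # centroids 0.05 / 0.95, per-point silhouettes (b-a)/max(a,b)
  expect_equal(q$davies_bouldin, (0.05 + 0.05) / 0.9)
  expect_equal(q$silhouette, mean(c((0.95 - 0.1) / 0.95, (0.85 - 0.1) / 0.85,
                                    (0.85 - 0.1) / 0.85, (0.95 - 0.1) / 0.95)))

  # identical overlapping clusters: silhouette cannot be positive
  set.seed(23)
  xx <- rep(rnorm(20), 2)
  q2 <- cluster_quality(xx, rep(c(0, 1), each = 20))
  expect_lte(q2$silhouette, 0)

  # far-separated tight blobs approach the ideal limits
  far <- c(rnorm(30, 0, 0.01), rnorm(30, 100, 0.01))
  q3 <- cluster_quality(far, rep(c(0, 1), each = 30))
  expect_gt(q3$silhouette, 0.99)
  expect_lt(q3$davies_bouldin, 0.01)

  expect_error(cluster_quality(rep(1, 10), rep(c(0, 1), 5)), "degenerate")
})

test_that("silhouette agrees with the cluster package", {
  skip_if_not_installed("cluster")
  set.seed(24)
  x <- matrix(rnorm(60), ncol = 2)
  labs <- rep(c(0, 1), each = 15)
  ours <- cluster_quality(x, labs)$silhouette
  ref <- mean(cluster::silhouette(labs + 1, stats::dist(x))[, "sil_width"])
  expect_equal(ours, ref)
})
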