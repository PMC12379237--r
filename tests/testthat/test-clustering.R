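test_that("window identity matches its definition and is symmetric", {
  expect_equal(window_identity("AKAK", "AKAK"), 1)
  expect_equal(window_identity("AKAA", "AKCC"), 0.5)
  # X never matches, and padded positions leave the denominator when both pad
  expect_equal(window_identity("XXAK", "XXAK"), 1)
  expect_equal(window_identity("XAAK", "AAAK"), 3 / 4)
  w <- random_windows(10, len = 20, seed = 2)
  for (i in 1:9) {
    expect_equal(window_identity(w[i], w[i + 1]), window_identity(w[i + 1], w[i]))
  }
  expect_error(window_identity("AK", "AKA"), "length")
})

test_that("greedy clustering merges identical windows and separates disjoint ones", {
  same <- rep("KAKAKAKAK", 5)
  cl <- greedy_cluster(same, 0.4)
  expect_equal(length(cl$clusters), 1)
  expect_equal(sort(cl$clusters[[1]]), 1:5)

  cl2 <- greedy_cluster(c("AAAA", "CCCC"), 0.4)
  expect_equal(length(cl2$clusters), 2)
  expect_equal(cl2$representatives, 1:2)
})

# independent oracle: plain all-pairs greedy pass over the same canonical
# order, using only window_identity
greedy_oracle <- function(seqs, thr) {
  ord <- order(seqs, seq_along(seqs))
  reps <- integer(0); assign <- integer(length(seqs))
  for (i in ord) {
    hit <- 0L
    for (ci in seq_along(reps)) {
      if (window_identity(seqs[reps[ci]], seqs[i]) > thr) { hit <- ci; break }
    }
    if (hit == 0L) { reps <- c(reps, i); hit <- length(reps) }
    assign[i] <- hit
  }
  assign
}

test_that("greedy clustering agrees with a brute-force greedy oracle", {
  seqs <- random_windows(12, len = 43, seed = 9)
  # add near-duplicates so some merges actually happen
  seqs <- c(seqs, paste0(substr(seqs[1], 1, 40), "AAA"),
            paste0("CC", substr(seqs[2], 3, 43)))
  cl <- greedy_cluster(seqs, 0.4)
  got <- integer(length(seqs))
  for (ci in seq_along(cl$clusters)) got[cl$clusters[[ci]]] <- ci
  expect_equal(got, greedy_oracle(seqs, 0.4))
})

test_that("clustering is order-independent, bounded, and exact at threshold 1", {
  seqs <- random_windows(15, len = 20, seed = 4)
  seqs[8] <- seqs[3]                      # one exact duplicate
  perm <- sample(seq_along(seqs))
  cl_a <- greedy_cluster(seqs, 0.4)
  cl_b <- greedy_cluster(seqs[perm], 0.4)
  part_a <- lapply(cl_a$clusters, function(ix) sort(seqs[ix]))
  part_b <- lapply(cl_b$clusters, function(ix) sort(seqs[perm][ix]))
  expect_setequal(vapply(part_a, paste, "", collapse = "|"),
                  vapply(part_b, paste, "", collapse = "|"))
  expect_lte(length(cl_a$clusters), length(seqs))

  # threshold 1.0: only exact duplicates can exceed identity 1 - never merges
  cl1 <- greedy_cluster(seqs, 1.0)
  expect_equal(length(cl1$clusters), length(seqs))
  # just-below-1 threshold merges exact duplicates only
  cl99 <- greedy_cluster(seqs, 0.999)
  expect_equal(length(cl99$clusters), length(seqs) - 1)
})

test_that("balance_and_split balances classes and is reproducible", {
  pos <- khib_windows(random_windows(3, 9, seed = 21), rep("positive", 3))
  neg <- khib_windows(random_windows(10, 9, seed = 22), rep("negative", 10))
  bs <- balance_and_split(pos, neg, test_fraction = 0.1, n_folds = 2, seed = 1)
  expect_equal(nrow(bs$windows), 6)
  expect_equal(sum(bs$windows$label == "positive"), 3)

  bs2 <- balance_and_split(pos, neg, test_fraction = 0.1, n_folds = 2, seed = 1)
  expect_identical(bs$windows$window, bs2$windows$window)
  expect_identical(bs$fold_assignments, bs2$fold_assignments)

  expect_error(balance_and_split(neg, pos), "insufficient negative")
})

test_that("splits are stratified to within one sample per fold and class", {
  pos <- khib_windows(random_windows(500, 43, seed = 31), rep("positive", 500))
  neg <- khib_windows(random_windows(500, 43, seed = 32), rep("negative", 500))
  # random 43-mers essentially never share 40 % identity: singleton clusters
  bs <- balance_and_split(pos, neg, test_fraction = 0.1, n_folds = 10, seed = 5)
  expect_equal(length(bs$test_indices), 100)
  expect_equal(sum(bs$windows$label[bs$test_indices] == "positive"), 50)
  lab_train <- bs$windows$label[bs$train_indices]
  counts <- table(bs$fold_assignments, lab_train)
  expect_true(all(abs(counts - 45) <= 1))
})
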