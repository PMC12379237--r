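test_that("generation is reproducible and respects the window contract", {
  cfg <- synthetic_config(50, 60, flank = 21, preset = "human", seed = 40)
  w1 <- generate_windows(cfg)
  w2 <- generate_windows(cfg)
  expect_identical(w1$window, w2$window)
  expect_equal(nrow(w1), 110)
  expect_equal(sum(w1$label == "positive"), 50)
  expect_true(all(nchar(w1$window) == 43))
  expect_true(all(substr(w1$window, 22, 22) == "K"))
})

test_that("the null preset plants no position-specific differences", {
  cfg <- synthetic_config(1000, 1000, flank = 5, preset = "null", seed = 41)
  win <- generate_windows(cfg)
  cp <- do.call(rbind, strsplit(win$window[win$label == "positive"], ""))
  cn <- do.call(rbind, strsplit(win$window[win$label == "negative"], ""))
  # per position, each residue frequency difference lies inside a 99 %
  # binomial CI around zero (pooled sd, z = 2.58)
  for (col in c(1, 3, 8, 11)) {
    fp <- table(factor(cp[, col], levels = khibkit:::AA20)) / 1000
    fn <- table(factor(cn[, col], levels = khibkit:::AA20)) / 1000
    se <- sqrt(2 * 0.05 * 0.95 / 1000)
    expect_true(all(abs(fp - fn) < 3.3 * se))   # Bonferroni-ish headroom, 20 cells
  }
})

test_that("the human preset plants its configured lysine enrichment", {
  # offset -1 (column 21) carries the maximum K delta of 0.145; average the
  # empirical delta over three seeded replicates of 2000+2000 windows
  deltas <- vapply(1:3, function(s) {
    win <- generate_windows(synthetic_config(2000, 2000, preset = "human",
                                             seed = s))
    cp <- do.call(rbind, strsplit(win$window[win$label == "positive"], ""))
    cn <- do.call(rbind, strsplit(win$window[win$label == "negative"], ""))
    mean(cp[, 21] == "K") - mean(cn[, 21] == "K")
  }, numeric(1))
  se <- sqrt(0.195 * 0.805 / 2000 + 0.05 * 0.95 / 2000)
  expect_lt(abs(mean(deltas) - 0.145), 2 * se / sqrt(3))

  # effect decays with distance: offset -21 delta is 0.145/21
  eff <- preset_effects("human")
  expect_equal(max(eff$delta[eff$residue == "K"]), 0.145)
  expect_equal(min(eff$delta[eff$residue == "K"]), 0.145 / 21)

  # species presets encode the printed maxima
  expect_equal(max(preset_effects("parasite")$delta), 0.135)
  expect_equal(max(preset_effects("plant")$delta[
    preset_effects("plant")$residue == "K"]), 0.127)
})

test_that("invalid effect configurations are rejected", {
  bad <- data.frame(offset = -1, residue = "P", delta = -0.06)  # below 1/20
  expect_error(synthetic_config(10, 10, effects = bad), "below 0")
  expect_error(synthetic_config(10, 10,
                                effects = data.frame(offset = 0, residue = "K",
                                                     delta = 0.1)))
})

test_that("synthetic proteomes round-trip through window extraction", {
  cfg <- synthetic_config(1, 0, flank = 21, preset = "human", seed = 43)
  gp <- generate_proteome(cfg, n_proteins = 10, protein_length = 200,
                          sites_per_protein = 3)
  expect_equal(nrow(gp$sites), 30)
  # every annotated site is a lysine
  for (i in seq_len(nrow(gp$sites))) {
    s <- gp$proteins$sequence[gp$proteins$accession == gp$sites$accession[i]]
    expect_identical(substr(s, gp$sites$position[i], gp$sites$position[i]), "K")
  }
  # extraction reproduces the implanted windows exactly
  win <- build_windows(gp$proteins, gp$sites, flank = 21)
  expect_identical(win$window, gp$windows$window)

  # negatives are all remaining lysines
  total_k <- sum(vapply(gp$proteins$sequence, function(s) {
    sum(strsplit(s, "")[[1]] == "K")
  }, numeric(1)))
  negs <- sum(vapply(seq_len(10), function(i) {
    acc <- gp$proteins$accession[i]
    nrow(enumerate_negative_windows(
      gp$proteins$sequence[i],
      gp$sites$position[gp$sites$accession == acc], flank = 21,
      accession = acc))
  }, numeric(1)))
  expect_equal(negs, total_k - 30)
})
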