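# khibkit

Prediction of lysine 2-hydroxyisobutyrylation (Khib) sites from protein
sequence.

Khib is an acyl post-translational modification that adds a
2-hydroxyisobutyryl group (+86 Da) to lysine side chains, neutralizing
their charge and reshaping chromatin and metabolic regulation. Mapping Khib
sites experimentally is slow and expensive, so computational site
prediction is used to prioritize candidate lysines for validation. khibkit
is an R toolkit for building and evaluating such predictors end-to-end, for
bioinformaticians who have (or want to simulate) a table of annotated sites
and a proteome.

## What it implements

Given proteins and annotated sites, the pipeline is:

1. **Windows** — padded, lysine-centred peptide windows of length
   `2·flank + 1` (default 43), `"X"`-padded at protein termini
   (`build_windows()`, `enumerate_negative_windows()`).
2. **Redundancy removal & balancing** — greedy identity clustering at 40 %
   (a CD-HIT-style reduction, `greedy_cluster()`), one representative per
   cluster, negatives sampled to a 1:1 ratio, stratified 90/10 split and
   10-fold assignment (`balance_and_split()`).
3. **Hybrid encoding** (1487 features by default,
   `build_feature_matrix()`):
   * CTD — composition / transition / distribution descriptors over seven
     three-group physicochemical partitions (147 features), with
     `C_i = n_i / L`, `T_ij = (#adjacent pairs across groups i,j) / (L−1)`,
     and `D` the relative positions of the 1st/25 %/50 %/75 %/last group
     occurrences;
   * AAindex — 20 property scales per position (860 features at L = 43);
   * embeddings — mean-pooled per-residue vectors from a pluggable
     provider (480 features); a deterministic offline provider is built in,
     and `embedding_adapter()` accepts any external protein language model.
4. **Feature selection** — empirical mutual information
   `I(X;Y) = Σ p(x,y) log p(x,y)/(p(x)p(y))` on equal-frequency bins,
   ranked descending, top 700 kept (`rank_and_select()`).
5. **Classification** — gradient-boosted decision trees (histogram
   binning, leaf-wise growth) with tuned defaults: 500 trees, learning
   rate 0.1, depth 11, 89 leaves (`booster_params()`, `train_booster()`,
   `cross_validate()`, `tune_booster()`).
6. **Evaluation** — ACC/SN/SP/PR/F1/MCC, Mann–Whitney ROC/AUC,
   Hanley–McNeil comparison of correlated AUCs, two-sample-logo position
   statistics, silhouette / Davies–Bouldin class-separation indices.

A synthetic generator (`synthetic_config()`, `generate_windows()`,
`generate_proteome()`) plants species-preset position-specific residue
enrichments (upstream K, E enrichment, P depletion, …) so the whole
pipeline runs and is testable offline.

## Worked example

```r
library(khibkit)

cfg  <- synthetic_config(n_pos = 500, n_neg = 500, preset = "human", seed = 1)
win  <- generate_windows(cfg)
feats <- build_feature_matrix(win)      # 1000 x 1487
sel  <- rank_and_select(feats, k = 700)
category_report(sel)
#>   esm   ctd aaidx
#> 34.57 10.43 55.00

cv <- cross_validate(feats, booster_params(), n_folds = 5, seed = 1,
                     select_k = 700)
round(cv$mean, 3)
#>   ACC    SN    SP    PR    F1   MCC   AUC
#> 0.754 0.738 0.770 0.764 0.749 0.510 0.849

logo <- two_sample_logo(win[win$label == "positive", ],
                        win[win$label == "negative", ])
subset(logo, offset == -1 & residue %in% c("K", "E", "P"))
#>     offset residue freq_pos freq_neg diff            p     flag
#> 407     -1       E    0.136    0.040  9.6 7.448522e-08 enriched
#> 412     -1       K    0.190    0.044 14.6 4.581430e-13 enriched
#> 415     -1       P    0.006    0.046 -4.0 7.022874e-05 depleted
```

The selection report says which feature families carry the signal (here
AAindex and embeddings dominate, CTD contributes ~10 %). The
cross-validated AUC of 0.85 shows the booster recovering the planted
human-preset motif; the logo rows confirm the planted effects at offset
−1 — K and E enriched, P depleted — with the expected magnitudes
(+14.6, +9.6 and −4.0 percentage points).

A thin command-line front end over the same functions is included at
`inst/cli/khibkit-cli.R` (`simulate`, `extract-windows`, `cluster`,
`balance-split`, `build-features`, `select-features`, `cv`, `logo`).

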