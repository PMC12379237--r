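---
title: "Predicting lysine 2-hydroxyisobutyrylation sites: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting lysine 2-hydroxyisobutyrylation sites: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Lysine 2-hydroxyisobutyrylation (Khib) is an acyl post-translational
modification that adds a 2-hydroxyisobutyryl group (+86 Da) to lysine side
chains, neutralizing their positive charge. Experimentally mapping Khib sites
by mass spectrometry is expensive, so sequence-based classifiers are used to
prioritize candidate lysines. The task is binary: given a fixed-length
peptide window centred on a lysine, predict whether that lysine is modified.

`khibkit` implements the whole pipeline — window construction, redundancy
removal, class balancing, hybrid feature encoding, mutual-information feature
selection, boosted-tree classification, and evaluation — with a synthetic
generator so every stage can be exercised offline, without curated proteomes
or pretrained embedding models.

## Peptide windows

Windows are `2*flank + 1` residues centred on the candidate lysine; the
default flank of 21 gives 43-residue windows, the length at which
cross-validated AUC plateaus in window-size scans of this family of
predictors (the package exposes `window_size_scan()` to repeat that analysis
on any dataset). Site positions are 1-based, matching UniProt convention.
Lysines closer than `flank` to a protein terminus are padded with `"X"`,
which is treated as "no residue" everywhere downstream: it never matches in
identity computations, contributes zero to position-specific encodings, and
is excluded from compositional denominators and logo frequencies. The
non-standard codes B, Z, U, O are mapped to `"X"` with a warning.

## Redundancy removal and balancing

Nearly identical training peptides inflate apparent performance, so windows
are clustered by greedy incremental identity clustering at a 40 % threshold:
windows are processed in canonical order (sorted by sequence, then accession,
then position — making the result independent of input order) and each
window joins the first cluster whose *representative* exceeds the identity
threshold, else founds a new cluster. Identity is defined as matching
non-pad positions divided by positions where at least one window has a
residue. This is a deliberate, documented simplification of the CD-HIT
algorithm (greedy, representative-based, same intent); it does not reproduce
CD-HIT's word-filter heuristics bit-for-bit.

Candidate negatives (all unannotated lysines) vastly outnumber positives.
`balance_and_split()` keeps one representative per positive cluster, samples
an equal number of negative cluster representatives without replacement
(seeded), and emits a stratified 90/10 train/test split plus a stratified
10-fold assignment in which per-fold class counts differ by at most one
sample.

## Feature encoding

Three complementary blocks are concatenated (default 1487 columns):

* **CTD (147)** — composition/transition/distribution descriptors over
  seven three-group physicochemical partitions of the amino-acid alphabet
  (hydrophobicity, van der Waals volume, polarity, polarizability, charge,
  secondary structure, solvent accessibility). Composition is the group
  fraction (3 values per attribute, summing to 1); transition is the
  frequency of adjacent pairs straddling two groups, divided by `L - 1`
  (3 unordered pairs per attribute); distribution is the relative position
  (× 100) of the 1st, 25 %, 50 %, 75 % and last occurrence of each group
  (15 values per attribute). The percentile occurrence index is
  round-half-up of `p * n`, clamped to `[1, n]`, which reproduces the
  standard worked examples (1.75 → 2, 3.5 → 4, 5.25 → 5). Note an
  asymmetry in the literature: the worked transition example is
  *directional* (group 1 → group 2 only) while the 21-dimensional feature
  vector requires *unordered* pair counting. Both are implemented
  (`ctd_transition(mode=)`); the symmetric form is the feature default,
  because only it yields 3 pairs × 7 attributes = 21 columns.
* **AAindex (860)** — each of the 43 positions is mapped to 20 numeric
  property scales (position-major, `"X"` → 0). The default table ships 20
  established published scales spanning hydrophobicity, volume, polarity,
  charge, electronic structure (EIIP), conformational propensity,
  flexibility, burial and mutability; any AAindex-style table can be
  substituted via `load_aaindex()`, since the optimal scale set is
  dataset-dependent.
* **Embeddings (480)** — a pluggable provider contract: any per-residue
  embedder with a fixed dimension, mean-pooled over non-pad positions. The
  built-in `offline_provider()` derives residue vectors deterministically by
  seeding a RNG from a hash of the residue identity and its local context
  k-mer (k = 3). It is a real, reproducible encoder of local sequence
  context — not a stand-in pretending to carry evolutionary information —
  and its 480-dimension default matches the width of the mid-size protein
  language model this pipeline is designed to plug in via
  `embedding_adapter()`.

No per-feature standardization is applied by default: the downstream tree
model is scale-invariant, and keeping raw values makes selected features
interpretable.

## Mutual-information feature selection

Each column is scored by the empirical mutual information with the label,
$I(X;Y) = \sum_{x,y} p(x,y)\log\frac{p(x,y)}{p(x)p(y)}$ in nats, after
discretizing the feature into at most 20 equal-frequency bins (bins collapse
for features with few distinct values; $0\log 0 \equiv 0$). Equal-frequency
binning makes the score invariant under monotone feature transforms, and the
direct plug-in estimator is deterministic, which matters for reproducible
ranking; only ranks are consumed downstream, so estimator bias is
immaterial. Features are ranked score-descending with index-ascending tie
breaks and the top `k = 700` are kept — around the plateau where adding
features no longer improves cross-validated AUC in this problem family; a
`k` scan is one `cross_validate(select_k=)` loop away. Selection inside
`cross_validate()` is re-run per fold on training data only, so the
held-out fold never influences feature choice.

## Classifier

The classifier is a gradient-boosted decision-tree ensemble consumed through
a thin contract (`booster_params()`, `train_booster()`, `predict_scores()`).
The engine is xgboost configured for histogram binning with leaf-wise
(best-first, `lossguide`) tree growth — the growth strategy that
distinguishes this family of fast boosters — under binary cross-entropy
loss. Defaults are the tuned operating point for this task: 500 trees,
learning rate 0.1, maximum depth 11, 89 leaves, L1 = 1.15e-5, L2 = 4.4e-8;
feature/row subsampling and the minimum-child control keep engine defaults.
`min_child_samples` is expressed in samples and mapped onto the engine's
hessian-sum control by the factor 0.25 (the maximum per-sample hessian of
logistic loss) — an approximation, documented here, exact at the start of
training. `tune_booster()` performs seeded uniform random search (log-scale
for the regularization strengths) over the tested ranges; with a hundred
trials this reliably locates the plateau for this problem class, and random
search keeps the procedure dependency-free and exactly reproducible.
Training is single-threaded by default so seeded runs are bit-reproducible
on one platform; multi-threaded training is available (`nthread`) at the
cost of bit-exactness.

The prediction threshold for confusion metrics is 0.5 (configurable);
prediction aligns feature columns by *name*, so column order cannot silently
corrupt scores.

## Evaluation

`confusion_metrics()` computes ACC, SN, SP, PR, F1 and MCC from the
thresholded confusion matrix (MCC is defined as 0 when its denominator
vanishes). `roc_auc()` computes AUC as the normalized Mann–Whitney
statistic with half credit for ties — identical to trapezoidal integration
of the step ROC. Two correlated AUCs measured on the same test set are
compared with the Hanley–McNeil z-test: each AUC's standard error uses
$SE^2 = \frac{A(1-A) + (n^+{-}1)(Q_1 - A^2) + (n^-{-}1)(Q_2 - A^2)}{n^+ n^-}$
with $Q_1 = A/(2-A)$, $Q_2 = 2A^2/(1+A)$, and the correlation term is
estimated as the mean of the within-positives and within-negatives Pearson
correlations of the two score vectors — a continuous surrogate for the
original table lookup, adequate at test-set sizes in the thousands.

`two_sample_logo()` compares per-position residue frequencies between
positive and negative windows via Welch t-tests on 0/1 occurrence
indicators (a two-proportion z alternative is provided; they agree
asymptotically), flagging enriched/depleted cells at α = 0.05 with **no**
multiple-testing correction — the convention of two-sample-logo analyses,
so individual flags at cells with tiny effects should be read accordingly.
`cluster_quality()` reports the mean silhouette width and the
Davies–Bouldin index of any 1-D score vector or low-dimensional embedding
against the class labels; it accepts either raw probabilities or externally
computed 2-D coordinates (the package deliberately does not implement
t-SNE).

## The synthetic generator

`synthetic_config()` + `generate_windows()` produce balanced window sets
from a uniform 1/20 background (no background composition is canonical for
this task; a custom vector can be supplied) with planted position-specific
frequency deltas. The species presets encode the qualitative motif biology
reported for real Khib data — upstream lysine enrichment with species
maxima of 14.5 % (human), 13.5 % (parasite) and 12.7 % (plant), glutamate
enrichment, proline depletion, parasite-specific alanine enrichment and
serine depletion, plant-specific arginine depletion — with each effect
maximal adjacent to the site and decaying linearly to ~0 at the window
edge. The decay shape is an explicit modelling choice; real positional
profiles are not linear. Two caveats follow from the uniform background:
depletions deeper than 5 percentage points are impossible (every residue
starts at 5 %), so the presets cap depletion deltas at 3.5–4 points where
real data shows 6–10; and after planting deltas at an offset the untouched
residues are proportionally renormalized, so large enrichments induce small
genuine depletions (~1 point) across other residues at the same position.
Passing tests on this generator demonstrate that the pipeline recovers
planted signal of realistic magnitude — not that it reproduces real-data
performance, which depends on curated proteomes and pretrained embeddings.

`generate_proteome()` embeds generated positive contexts into random
proteins at recorded, non-overlapping lysine positions so the full
FASTA-to-windows path round-trips exactly.

## Problem sizes and numerical choices

The shipped test-suite exercises the full pipeline at 2000+2000 windows
(human preset, 10-fold CV with per-fold selection of 700 of 1487 features)
and the chance-level check at 1000+1000 (null preset); unit tests use small
boosters (tens of trees) because booster size is irrelevant to the
properties under test. Deterministic behaviours asserted exactly: seeded
generation, clustering under canonical order, fold assignment, single-thread
training. Stochastic assertions use binomial/normal error bounds derived
from the generator, averaged over a few seeded replicates where a single
draw would be fragile. Degenerate inputs have defined behaviour throughout:
all-pad windows error, absent CTD groups yield zeros, MCC's 0/0 is 0,
constant features score zero MI, and identical score vectors give a
Hanley–McNeil z of exactly 0.

## Known limitations

* The greedy clusterer is O(n·clusters) with a plain representative scan;
  for very large negative pools CD-HIT itself is preferable, and the
  results will differ in detail.
* The offline embedding provider encodes local composition/context only; it
  cannot carry the long-range evolutionary signal a pretrained transformer
  provides, so absolute AUCs on synthetic data understate what the hybrid
  feature set achieves on real proteomes with real embeddings.
* The Hanley–McNeil correlation surrogate and the sample-to-hessian mapping
  of `min_child_samples` are documented approximations.
* Species presets plant first-order (per-position, per-residue) effects
  only; real motifs include higher-order dependencies.
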