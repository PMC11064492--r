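---
title: "Methods: predicting microbial cross-feeding and competition from reaction profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: predicting microbial cross-feeding and competition from reaction profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metapairs)
```

## The problem and the model

Whether two microorganisms cross-feed (one grows on metabolites the other
secretes) or compete (both contend for the same resources) is strongly
constrained by their metabolic capabilities, and those capabilities can be
read off a genome-scale metabolic network. `metapairs` treats interaction
prediction as supervised two-class classification on reaction
presence/absence:

1. **Reaction pool.** An ordered reference universe of reaction identifiers
   (for gut microbes, typically the AGORA namespace) is filtered to the
   reactions present in at least one organism of the study; the filtered,
   ordered list of $P$ reactions defines the vector coordinates. The order
   and a content hash are serialized with every artifact, because the
   coordinates are meaningless without them. The alternative reading of the
   filter — keep reactions present in *every* organism — would produce
   near-empty, constant-feature pools and is rejected; only reactions no
   organism carries are dropped.
2. **Profiles.** Organism $i$ becomes a binary vector $x_i \in \{0,1\}^P$
   with $x_{ij} = 1$ iff pool reaction $j$ is in its network. Reactions an
   organism carries outside the pool (exchange and sink reactions emitted by
   reconstruction tools) are counted and ignored rather than treated as
   errors.
3. **Pair vectors.** A pair $(A, B)$ is the concatenation
   $x_A \,\|\, x_B \in \{0,1\}^{2P}$. Because concatenation is ordered and
   the interaction label is not, every labelled pair enters the dataset
   twice — $A\|B$ and $B\|A$ — which removes the positional bias and doubles
   the sample size. Each unordered pair carries a canonical key (sorted
   identifier pair), the unit at which all train/test bookkeeping happens.

With a curated set of 1,053 cross-feeding and 273 competition pairs this
yields 2,106 + 546 = 2,652 oriented vectors; at $P = 3{,}141$ each vector
has 6,282 coordinates.

## Leakage-aware cross-validation folds

The two orientations of one pair are near-duplicates; letting them straddle
a train/test split would leak the answer. `metapairs` makes the co-location
rule structural: fold assignment is a map from the unordered pair key, so an
orientation can never be separated from its twin. `audit_leakage()`
nevertheless re-checks any assignment (including ones loaded from disk),
because assignments are data.

Two fold constructors are provided:

* `cluster_pairs()` + `assemble_folds()` — k-means (squared Euclidean on the
  raw 0/1 vectors, 10 restarts, fixed seed, 100 iterations) on the
  *canonical* orientation of each pair, followed by a deterministic greedy
  merge of whole clusters into folds: largest cluster first (ties by cluster
  id) into the currently smallest fold (ties by fold index). The greedy rule
  replaces a manual merge step for reproducibility; it balances example
  counts only, not class counts, since published four-fold splits of this
  kind are themselves visibly class-unbalanced. Keeping similar pairs inside
  one fold makes the evaluation measure generalization *across* groups of
  similar pairs.
* `random_folds()` — a uniform pair-level partition. Orientation
  co-location still holds, but similar pairs may sit on opposite sides; this
  measures within-distribution recovery.

Both report per-fold tallies over oriented vectors. A consequence of strict
pair-level assignment worth noting: per-fold oriented counts are always
even, since each pair contributes its two orientations to one fold.

## The KNN baseline

k-nearest-neighbours is the in-package reference classifier, implemented
directly (not wrapped) so it can be verified against an exhaustive
neighbour-sort oracle in the test suite. Configuration:

* `k` (default 3), selected by `select_k()`: a single held-out split
  (default 67% train / 33% test, optionally on a random subsample of pairs,
  e.g. 10%) that respects orientation co-location; the accuracy-maximising
  `k` is returned with ties broken toward smaller `k`. Two split
  conventions exist in practice (a fraction of the whole set vs a fraction
  of one fold); both are expressible through `train_fraction` and
  `subset_fraction`, and the 67/33-on-a-subsample reading is the default.
* metric: Euclidean or cosine on the raw 0/1 vectors; voting: uniform or
  inverse-distance with $w_i = 1/(d_i + 10^{-12})$, the $\varepsilon$
  guarding exact duplicates. The reported default is `k = 3`, Euclidean,
  uniform; all four metric/weighting combinations remain runnable because
  published accounts of which combination won are typically silent.
* the score is the (weighted) fraction of neighbours labelled
  cross-feeding; the label is cross-feeding when the score reaches the 0.5
  threshold, which also resolves exact vote ties toward the majority class
  under the curated prevalence (~3.86:1).
* numerical tie-break: distances are snapped to 12 significant digits
  before ranking, so exact ties — frequent on binary data — resolve by
  stable training-row order regardless of the summation order of the
  underlying BLAS; remaining ties at the k-th neighbour are included in
  training-row order.

Other families (random forest, SVM with linear/RBF/polynomial/sigmoid
kernels, gradient boosting) enter through `classifier_spec()` as thin
adapters over `randomForest`, `e1071` and `xgboost`: the package's
contribution is the encoding, fold construction and evaluation pipeline,
not a re-derivation of those solvers. A missing engine raises a capability
error; there is no silent fallback. Seeds are mandatory for every family
whose training (or probability calibration) is stochastic.

At inference time `predict_pair()` scores both orientations and averages,
so predictions are exactly orientation-invariant; `predict_all_pairs()`
covers the $\binom{m}{2}$ unordered pairs of a profile collection.

## Evaluation

All scalar metrics derive from the four pooled confusion counts
(`tp_co`, `fn_co`, `fn_cf`, `tp_cf`): per-class precision, recall and F1
with each class in turn as target, accuracy, and balanced accuracy (mean of
the two recalls — the honest summary under ~4:1 imbalance). Counts are
pooled over folds before metrics are computed, the convention that
reproduces published tables of this kind exactly; per-fold panels can be
obtained by applying `panel_from_counts()` to per-fold counts. Zero
denominators yield 0 with an explicit flag rather than `NaN`, keeping
reports machine-readable. Display rounding is two decimals, half-up, with
trailing zeros trimmed ("0.896" prints as "0.9").

ROC curves sweep every unique score; the area uses the trapezoidal rule and
therefore equals the normalized Mann–Whitney statistic (the test suite
checks this against a pairwise-comparison oracle and against `pROC`). PR
areas use the step-wise average-precision convention
$\sum_i (R_i - R_{i-1}) P_i$; linear PR interpolation is known to be
optimistic and is deliberately not offered. The random-prediction floor for
each class equals its prevalence (0.21 / 0.79 at the curated class ratio) —
`random_baseline_precision()` computes it so reported precisions can be
read against chance.

## Consensus against external score matrices

A potential cooperation score (PCPS) matrix is transformed by the sign
trichotomy — positive to cross-feeding, zero to none, negative to
competition — which is invariant under positive rescaling. The consensus of
two label matrices is $+1$ where both say cross-feeding, $-1$ where both
say competition, $0$ otherwise. `score_against_reference()` compares a
predicted label matrix to a reference, by default discarding pairs the
reference marks as no interaction, because the predictor itself is strictly
two-class ("none" is representable but never trained on). With
`discard_none = FALSE`, every off-diagonal pair enters the scored count and
the full-agreement accuracy, while the two-class confusion counts still
cover only reference-labelled pairs. If a score matrix is asymmetric, the
upper-triangle entry defines the unordered pair's label.

## The synthetic community generator

Real curated interaction sets require hundreds of genomes and their
reconstructions, so the generator produces communities with a *planted*,
tunable signal at the same scale: pool of 3,141 reactions, mean of 793
reactions per organism, 260 organisms, 1,053 + 273 interaction records by
default.

Structure, all of it expressed in reaction presence only (never in
identifiers or vector order):

* **Trait blocks.** A small set of exchangeable metabolites (default 6)
  each define a producer and a consumer pathway block of `module_size`
  reactions (default 100 — the scale of a sizeable pathway); a set of
  resource blocks (default 6) represent shared nutrient-acquisition
  pathways. Each organism gets one producer, one consumer, and (with
  probability 0.6) one resource block.
* **Clade cores.** Each organism belongs to one of 12 families sharing a
  core of 150 background reactions, each member retaining a core reaction
  with probability 0.85; the remainder of the network is individual uniform
  background filled to the target mean. The cores give pair clustering
  label-independent phylogenetic structure to latch onto, as in real
  communities; without them, the only clusterable structure would be the
  label-bearing blocks themselves and cluster-based folds would
  degenerately isolate every trait combination.
* **Labels from rules.** A pair cross-feeds when one organism produces a
  metabolite the other consumes (and they share no resource); it competes
  when both carry the same resource block (and no complementarity).
  `plant_interactions()` samples the requested record counts from
  rule-satisfying pairs. An earlier design inserted blocks into organisms
  per labelled pair; with ~10 interactions per organism that saturates
  every organism with most blocks and destroys the signal, which is why
  labels are derived from persistent organism-level traits instead.
* **Noise dials.** `alpha`/`beta` are the probabilities that a
  cross-feeding/competition record actually satisfies its rule (the
  remainder are structureless pairs); `eta` flips each record's label after
  sampling. At `eta = 0.5` the labels carry no signal and any classifier's
  cross-validated balanced accuracy must sit at chance — the `null` preset
  packages this control.
* **Determinism.** All randomness flows from one master seed through named
  sub-streams, so the community and the interaction sampling are
  independently reproducible; a fixed seed reproduces the bundle
  byte-for-byte, and every pool reaction is guaranteed present in at least
  one organism so the working pool equals the synthetic pool exactly.

What the generator does *not* emulate: flux feasibility or thermodynamics,
metabolite-level mechanism, reaction co-occurrence beyond clade cores and
blocks, uneven clade sizes, and the annotation noise of real
reconstructions. Passing the planted-recovery checks therefore shows the
pipeline recovers a clean combinatorial signal at realistic dimensions — it
does not certify accuracy on real genomes.

Two recovery quantities are deliberately kept distinct wherever the
synthetic community is evaluated. Under `random_folds()` the planted signal
is recoverable (every trait combination is represented on both sides of
each split), and this is the generator's noise-free recovery gate. Under
clustered folds the evaluation asks the classifier to generalize across
clades; that number is computed and reported separately and is expected to
be lower. Conflating the two would either hide leakage-avoidance (random
folds only) or make the gate measure fold hardness rather than signal
recovery (clustered folds only).

## Problem sizes used by the checks

The test suite and the acceptance script run the full default scale for
dataset-construction arithmetic and the recovery gate (2,652 vectors of
6,282 coordinates), and reduced scales elsewhere: the label-noise sweep and
the null control use the `null` preset (pool 500, 100 organisms, 602
records), oracle comparisons use a few hundred random vectors, and
permutation nulls use 500–1,000 shuffles. These sizes were chosen so each
property is measured with comfortable statistical margin while the whole
suite stays quick to run.

## Known limitations

* Two-class only: "no interaction" is never predicted, so comparisons to
  three-state references are made on the reference's labelled pairs.
* The KNN score takes at most $k+1$ distinct values, so its ROC/PR curves
  are coarse at small $k$.
* Greedy fold balancing is a heuristic; a single dominant cluster can make
  balanced folds unachievable (it warns rather than errs).
* Organism identifiers must avoid `|` and whitespace, which the canonical
  pair key uses as a separator.
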