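# metapairs

Predicting pairwise microbial interactions — cross-feeding vs competition —
from genome-scale metabolic networks.

## The problem

Microbial communities are shaped by metabolic interactions: one organism
may grow on metabolites another secretes (cross-feeding), or two organisms
may contend for the same substrates (competition). Measuring these
interactions experimentally is slow; inferring them from genomes is not.
`metapairs` is for microbiome and systems-biology researchers who have
already-reconstructed metabolic networks (SBML models or plain reaction-ID
lists) and curated interaction labels, and who want to train, evaluate and
apply a classifier of interaction type — or to benchmark such classifiers
on synthetic communities with a planted, tunable signal.

## The method

* Each organism is encoded as a binary vector over a shared ordered
  reaction pool: `bits[j] = 1` iff pool reaction *j* is present in its
  network. The pool is a reference universe filtered to reactions present
  in at least one organism of the study.
* A pair (A, B) is the concatenation `x_A || x_B` of the two profiles
  (length 2P), and every labelled pair enters the dataset in both
  orientations (AB and BA), removing positional bias and doubling the
  sample; at P = 3,141 this gives pair vectors of 6,282 bits.
* Cross-validation folds are built at the unordered-pair level — the two
  orientations of a pair can never straddle a train/test split — either by
  k-means clustering of pair vectors followed by a deterministic greedy
  merge (generalization across groups of similar pairs) or by a random
  pair-level partition (within-distribution recovery). Every assignment is
  auditable with `audit_leakage()`.
* The baseline classifier is an in-package k-nearest-neighbours (k = 3,
  Euclidean or cosine, uniform or inverse-distance voting) with a
  `select_k()` tuning procedure; random forest, SVM (four kernels) and
  gradient boosting run behind the same contract via established
  implementations.
* Evaluation pools confusion counts over folds and derives per-class
  precision/recall/F1, accuracy, balanced accuracy, ROC and PR curves with
  areas, plus the random-prediction precision floor (the class prevalence).
* Predicted interaction matrices can be compared against external
  potential-cooperation-score (PCPS) matrices through a sign trichotomy
  (positive = cross-feeding, zero = none, negative = competition) and a
  consensus matrix (+1 / −1 / 0).

## Worked example

A full run on a synthetic community at the curated-study scale (260
organisms, pool of 3,141 reactions, 1,053 cross-feeding + 273 competition
records, noise-free planted signal):

```r
library(metapairs)
bundle   <- make_fixture("paper_scale", seed = 1)
pool     <- build_reaction_pool(bundle$pool, bundle$organisms)
profiles <- encode_profiles(bundle$organisms, pool)
dataset  <- augment_dataset(bundle$records, profiles)
print(dataset)
#> <pair_dataset> 2652 oriented vectors (1326 pairs) of length 6282
#>   class counts: cross_feeding = 2106, competition = 546

folds <- random_folds(dataset, n_folds = 4, seed = 1)
cv    <- cross_validate(classifier_spec("knn", list(k = 3)), dataset, folds)
print(cv)
#> <cv_result> knn
#> <confusion_counts> tp_co=462 fn_co=84 fn_cf=24 tp_cf=2082
#> <metric_panel>
#>   competition:   P=0.95 R=0.85 F1=0.9
#>   cross_feeding: P=0.96 R=0.99 F1=0.97
#>   accuracy=0.96 balanced_accuracy=0.92

round(random_baseline_precision(dataset$class_counts), 2)
#> cross_feeding   competition
#>          0.79          0.21
```

Reading the numbers: augmentation doubled 1,326 records into 2,652 oriented
vectors of length 2 × 3,141. Pooled over the four leak-free folds, 3-NN
recovers the planted signal (accuracy 0.96, balanced accuracy 0.92) — far
above the prevalence floors of 0.21/0.79 a label-agnostic predictor would
attain. Swapping `random_folds()` for `cluster_pairs()` +
`assemble_folds()` asks the harder question of generalization across
clusters of similar pairs and yields lower numbers.

A command-line interface over the same functions ships in
`inst/cli/metapairs.R` (`simulate`, `encode`, `make-folds`,
`cross-validate`, `consensus`, `run`).

## Scope

The package consumes already-reconstructed networks. Genome download,
metabolic reconstruction (AuReMe/AGORA mapping and the like) and flux
simulation are out of scope, as is reproducing results that require the
external genome collections themselves.
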