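---
title: "Comparative physicochemical profiling and substrate prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative physicochemical profiling and substrate prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

Intramembrane proteases such as γ-secretase cleave dozens of single-span
membrane proteins without any recognizable consensus motif. What
distinguishes a substrate from a non-substrate is not a sequence pattern
but a diffuse physicochemical signature spread over the transmembrane
domain (TMD) and its flanking juxtamembrane regions (JMDs). `cpprofiler`
implements a complete, interpretable pipeline for learning such
signatures from two groups of proteins and projecting them back onto
individual residues.

```{r setup, eval = FALSE}
library(cpprofiler)
```

## The model

### Parts, splits, scales

Each protein enters as a sequence with annotated TMD boundaries and a
training label (positive, negative, or unlabeled). The pipeline requires
at least ten residues on either side of the TMD, the **JMD-N** and
**JMD-C**; entries with shorter flanks are dropped with a logged reason,
never padded. From a validated entry nine **parts** are derived: the TMD,
its N- and C-terminal halves (an odd-length TMD gives its extra residue
to the N-half — a convention the package fixes once and applies
everywhere), the TMD extended four residues into each flank, the two
JMDs, and their combinations. The first four residues of the JMD-C form
the **TMD-C anchor**, where basic residues typically pin the helix at the
membrane-water interface.

A **split** selects a residue subset of a part:

* **segments** — the part cut into 1–15 equal pieces (120 splits);
* **patterns** — 2–4 residues separated by 3 or 4 positions (one or two
  helical turns), anchored from either terminus, confined to a 15-residue
  window (182 splits);
* **periodic patterns** — every 3rd, 4th, or alternating 3rd/4th residue
  across the whole part, from either terminus (28 splits).

The enumeration is a pure function of its parameters and totals 330
splits with stable integer ids. A split that does not fit a part (its
span exceeds the part length) is *not applicable*: the feature value is
undefined there, never imputed as zero, because averaging over zero
residues has no meaning.

A **scale** assigns each amino acid a min-max-normalized property value
(charge, volume, helix propensity, …) and carries a category/subcategory
classification. A **feature** is one part-split-scale triple; its value
for a protein is the mean scale value over the split-selected residues,
always in [0, 1].

### The four filtering steps

With the three default parts (TMD, JMD-N + TMD-N, TMD-C + JMD-C), 330
splits, and a 133-scale set, `cpp_feature_space()` creates 131,670
features. `cpp_run()` then filters them:

1. **Pre-filter.** Features whose standard deviation across the *test*
   group exceeds `max_std_test` (default 0.2) are removed — a feature
   that varies wildly within the group it is meant to characterize
   carries no group signal. Of the survivors, the
   `floor(pct_pre_filter × n_created)` features with the largest
   *absolute* mean difference between test and reference are kept
   (6,583 at the defaults). The absolute value is used because features
   depleted in the test group are as informative as enriched ones.
2. **Ranking.** Every surviving feature is scored by the **adjusted
   AUC**: the rank-sum (Mann-Whitney) AUC of test against reference
   values, ties counted ½, shifted by −0.5 into [−0.5, 0.5]. ±0.5 means
   complete separation; the sign carries direction. Features are ranked
   by absolute adjusted AUC, ties broken by absolute mean difference and
   then feature id, so the ranking is total and deterministic.
3. **Redundancy filter.** A greedy scan accepts features in rank order;
   a candidate is rejected only if some accepted feature overlaps it
   positionally (Jaccard index of reference-frame positions above
   `max_overlap`, default 0.5) *and* is physicochemically equivalent
   (same scale subcategory, or absolute scale-vector correlation above
   `max_cor`, default 0.5). The conjunction matters: positional overlap
   alone is fine when the scales measure different properties, and the
   same scale reappearing at a different site is new information. The
   scan stops at `n_filter` (default 100) accepted features, which makes
   the accepted set for a smaller `n_filter` a strict prefix of that for
   a larger one.

The redundancy criterion could also be read disjunctively; the
conjunctive form was chosen because the disjunctive one collapses almost
all positional neighbourhoods onto a single representative and empties
the profile. Whether correlation is compared signed or absolute is a
second open choice; the package uses the absolute value, since an
anti-correlated scale duplicates the same physicochemical axis.

### Positional projection

For visualization and per-residue attribution, every feature is resolved
on a fixed reference frame: JMD-N (10) | TMD (20) | JMD-C (10), 40
positions. A feature's importance is divided equally among its resolved
positions; per-position sums give the profile, and per-(subcategory,
position) aggregation gives the feature maps. The projection conserves
total importance to arithmetic tolerance, which the tests assert.

## Deterministic positive-unlabeled learning

Substrate datasets are chronically imbalanced: tens of verified
substrates, a handful of verified non-substrates, hundreds of proteins
with unknown status. `dpulearn()` fills the gap deterministically. The
feature matrix is column-standardized (toggleable; features on [0, 1]
still differ in variance and PCA is scale-sensitive) and compressed by
PCA. The retained components are the smallest set explaining ≥ 80% of
variance (overridable). Each component receives a quota of selections
proportional to its explained-variance share — largest-remainder
rounding, earlier components winning remainder ties — and fills its
quota with the unlabeled proteins farthest (absolute 1-D distance on
that component) from the mean coordinate of the positives, ties broken
by sample id. There is no randomness anywhere, so reruns are
byte-identical. PCA is fit on all samples (positives, negatives,
unlabeled); fitting on positives + unlabeled only was the alternative,
and the all-samples choice was made because the known negatives carry
real information about the data manifold.

`pu_benchmark()` quantifies the value of this determinism: a seeded
evaluation subset of the unlabeled pool is reserved *before* any
selection, then a nearest-neighbour classifier is trained on positives
versus either the dPULearn negatives or repeated uniform random draws
from the remaining pool, and balanced accuracy on the reserved samples'
true classes is compared (two-sided one-sample t-test of the random
draws against the deterministic point value). A nearest-neighbour
learner is used deliberately: it is maximally sensitive to mislabeled
training points, and mislabeled hidden positives are precisely the
failure mode random sampling exhibits and distance-based selection
avoids. A regularized linear model would shrug off 20% label noise and
measure nothing.

## The training harness

`monte_carlo_train()` runs 25 seeded rounds. Each round splits the
labeled data into a stratified 80/20 train/test partition, ranks
features by random-forest importance on the training split, and for each
of ten model types selects the number of top-ranked features (grid,
default {50, 100}) and the hyperparameters (small fixed per-model grids)
by stratified 5-fold cross-validated balanced accuracy, refits on the
full training split, and evaluates on the held-out 20%. Ten model
families cover the usual inductive biases: four tree-based (CART, random
forest, extremely randomized trees, gradient boosting), two linear
(ridge and lasso logistic regression), an RBF support vector machine, a
single-hidden-layer perceptron, and two ensembles (bagged trees and
soft-voting over heterogeneous learners). The default run therefore fits
exactly 250 final models. Exact hyperparameter grids are a frozen
configuration choice, deliberately small so that grid search remains a
genuine but cheap inner loop.

Prediction scores average the positive-class probability over models,
with one discipline enforced throughout: a protein that was part of
training only receives predictions from rounds in which it sat in the
held-out split. The tests verify this by instrumentation (the
contributing-model count of every labeled protein must equal 10 × its
held-out round count). Scores from several independently trained
approaches are combined by `aggregate_approaches()` as mean ± sample
(n−1) standard deviation, and mapped to confidence classes: HC substrate
(≥ 0.8), LC substrate (≥ 0.5), LC non-substrate (> 0.2), HC
non-substrate (≤ 0.2).

## Explanation layer

SHAP values decompose one protein's prediction into additive per-feature
impacts around a base value. The package implements path-dependent
TreeSHAP over a unified tree representation extracted from all four
tree-model types; forest node covers are obtained by routing the
training matrix down each tree, and gradient boosting is explained on
its margin with thresholds snapped back to the single precision the
library stores internally. Additivity — base value plus a row's impacts
equals the model output — holds to well below 1e−6 per model and sample,
and is asserted in the tests both against each library's own
predictions and against a brute-force Shapley enumeration on small
trees. For the explanation layer all four models are fit with
probability-scale outputs (gradient boosting on the squared-error
objective) so their attributions share one scale and can be averaged
across models and rounds.

Per-protein impacts are normalized by the sum of absolute values (signs
preserved, absolute values summing to 1), and feature importance is the
mean absolute SHAP value over samples. For a protein *outside* the
training labels, **fuzzy labeling** includes it in training with a label
that flips across rounds: positive in `floor(score × n_rounds)` rounds —
the floor, not rounding, reproduces the defining example of a 22% score
giving 5 of 25 positive rounds — and negative otherwise. The positive
rounds are placed first; the placement is arbitrary in principle, and a
deterministic prefix keeps reruns identical while the per-round seeds
still vary the models.

## The synthetic data generator

`synth_dataset()` emulates a substrate-discrimination study: single-span
proteins with a hydrophobic-core TMD (lengths 19–25, composition biased
to L/I/V/F/A), mixed-composition JMDs of ten residues, and short random
ectodomain/cytosolic tails. Proteins carrying the positive signature
replace, independently per position with probability ε (the effect
size), the TMD-C anchor by K/R, the N-terminal TMD half by G/A/S, and
the last four TMD residues by V/I/T — an idealization of the
helix-destabilizing, small-residue, anchor-charge signature expected to
separate substrates from non-substrates. A fifth of the unlabeled pool
secretly carries the signature, so the positive-unlabeled setting is
realistic. `synth_scaleset()` provides random normalized scales with
subcategory labels, anchored by one charge-like, one size-like, and one
branched-hydrophobicity-like scale so the planted signature is
detectable in scale space.

What the generator does *not* emulate: real amino-acid covariance along
the helix, homology between proteins, annotation noise in TMD
boundaries, and the biological coupling between regions. Passing tests
on synthetic data therefore demonstrate that the machinery recovers a
known signal under controlled conditions — not that any particular
biological claim transfers.

## Problem sizes and numerical choices

The packaged checks run the study at its natural size — 63 positives, 14
known negatives, 631 unlabeled, 25 training rounds, 250 final models —
with a 25-scale synthetic scale set for the pipeline stages (the full
131,670-feature space is exercised where the combinatorics themselves
are under test). Replicated properties (positional recovery, the
zero-effect null) use 20 seeds with a reduced harness (3 rounds, the
four fastest model families) for the null, asserting the seed-aggregated
balanced accuracy. At zero effect the aggregate sits near 0.6 rather
than 0.5: comparative profiling selects features on *all* labeled
positives before the train/test split, a mild selection optimism
inherent to the design (the original workflow shares it), distinct from
train/test leakage — which the out-of-fold instrumentation rules out.

Other numerical choices: NA cells (splits not applicable to a protein's
part length) are excluded from means and standard deviations, and
mean-imputed only where a downstream model cannot accept missing values;
ties in every ranking are broken by id so all orderings are total;
quotas use largest-remainder rounding; the scale-selection search scans
cluster counts upward from the number of subcategories, so the returned
set is the smallest that covers every subcategory with cluster medoids
(ties to the lexicographically smallest id).

## Limitations

* Topology and TMD boundaries are consumed as annotation, never
  predicted; disagreement between annotation sources is handled by
  running the pipeline once per source and aggregating scores.
* Sequence-redundancy reduction (e.g. clustering at 40% identity) is a
  documented pre-processing hook for the user; the package does not
  reimplement it.
* The scale-selection procedure reproduces the published *algorithmic*
  constraint (every subcategory covered by a cluster medoid); curated
  scale sets themselves are data artifacts to be supplied by the user.
* Tree-SHAP is exact for the implemented tree families; kernel- or
  linear-model approximations are intentionally out of scope, so only
  tree-based models contribute to explanations.
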