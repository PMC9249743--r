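---
title: "CNN-feature random forests: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CNN-feature random forests: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The model

`cnnforest` classifies two-class grayscale image cohorts with a hybrid
of deep feature extraction and a from-scratch random forest.  The
pipeline inside one cross-validation iteration is:

* **Preprocessing.** Every image is collapsed to a single channel
  (luminance average), scaled to [0, 1] by its bit-depth maximum, and
  resampled to a fixed input shape (reference 100×100) with bilinear
  interpolation.
* **Feature generation.** The training fold $f_k$ is partitioned into
  $n$ disjoint, class-stratified subsets.  CNN $C_i$ trains on
  $f_k - f_{ki}$ and validates on $f_{ki}$, which forces the $n$
  networks apart through distinct training sets on top of distinct
  seeds.  Each CNN is deliberately small: conv(32, 3×3, stride 2) →
  ReLU → conv(64, 3×3, stride 2) → ReLU → dense(128) → ReLU →
  linear(1).  The scalar output is a margin trained with hinge loss on
  targets $\pm 1$, with an L2 penalty of 0.001 on all weight matrices.
* **The feature matrix.** Scoring all $|f_k|$ fold images with all $n$
  CNNs yields $P \in \mathbb{R}^{|f_k|\times n}$ — including each
  CNN's own validation images, which is intentional: $P$ must cover the
  whole fold so the forest sees every training sample.
* **The forest.** Fifteen trees are grown on $P$.  At each impure node
  the builder draws $\lceil\sqrt{n}\rceil$ candidate splits; a
  candidate is a uniformly random feature column paired, as threshold,
  with that column's value at a uniformly random sample in the node.
  The candidate minimising the child-size-weighted mean Gini impurity
  $I_G = 1 - \sum_i p(i)^2$ wins; rows with value ≤ threshold go left.
  Nodes stop at zero impurity, at `max_depth`, below
  `min_samples_leaf`, or when no candidate separates the rows.
* **Prediction.** A test image is scored by the $n$ CNNs and each tree
  votes; the majority decides, and the fraction of positive votes is
  the continuous score used for AUC.

### Assumptions

The method assumes (i) binary labels that are constant within a
patient, (ii) enough images per fold that a $1/n$ validation split
still contains both classes, and (iii) that a scalar CNN margin is an
informative summary of an image.  It does not assume calibrated
margins — trees are invariant to monotone transforms of each feature,
which is also why the raw margin (not a sigmoid of it) is the feature.

## Parameters that matter

| Parameter | Default | Why |
|---|---|---|
| `n_cnns` | 10 | reference setting; more CNNs = more feature columns |
| `folds` | 5 | stratified patient-grouped CV |
| `filters`, `dense_units` | 32/64, 128 | the reference architecture |
| `epochs` | 10 | reference budget per CNN |
| `batch_size` | 256 | reference value, tied to a ~57k-image fold (see below) |
| `optimizer` | adam (0.001); adagrad (0.01), rmsprop (0.001) | standard step sizes of the cited optimizers |
| `l2_coefficient` | 0.001 | hinge-loss regulariser of the reference setup |
| `n_trees` | 15 | reference forest size; odd, so binary votes cannot tie |
| `candidates_per_node` | ⌈√n⌉ | classification-forest convention (36 features → 6) |
| `bootstrap` | on | per-tree row resampling with replacement |
| `max_depth`, `min_samples_leaf` | 16, 1 | bounded recursion, otherwise grow to purity |

### Batch size and scaled-down budgets

"Train for 2 epochs" is only meaningful relative to the number of
optimizer steps an epoch contains.  The reference configuration pairs
batch 256 with ~57,000 fold images — about 220 updates per epoch, i.e.
a batch of ~0.45% of the training set.  The desk-scale configuration
(`desk_pipeline_config()`: 40+40 patients × 8 images, 32×32, 4 CNNs,
2 epochs) therefore uses batch 2 on its 384-image per-CNN training
sets, preserving that ratio; keeping batch 256 would collapse "2
epochs" into four SGD updates, which is a scale distortion rather than
a scale-down.  The equal-budget baseline, likewise, is budgeted in
epochs (n × epochs per fold), not wall-clock seconds: epoch counts are
hardware-independent and testable, wall-clock is neither.

## The synthetic cohort

`generate_cohort()` emulates exactly the statistical structure the
learning machinery relies on, and nothing more:

* patients contribute several images sharing a patient-specific smooth
  background (two low-frequency sinusoids with random orientation,
  phase and DC offset) — this makes patient-level leakage *detectable*:
  a model that memorises backgrounds looks perfect on leaked splits and
  ordinary on grouped splits;
* positive-class images additionally contain 1–3 bright ellipses with
  raised-cosine profiles (peak added intensity `lesion_intensity`,
  semi-axes ~`lesion_radius_px`), echoing how contrast lesions mark
  disease in real scans;
* pixel noise is additive Gaussian (`noise_sd`), clipped to [0, 1];
* the class ratio, images-per-patient and patient counts are free, so
  the cohort can mirror a 722:502-patient imbalance or shrink to desk
  scale.

It is *not* a physical MR simulation: the four sequence types are
emitted as metadata tags only, intensities have no physics, and lesion
morphology is cartoonish.  A green end-to-end test therefore
establishes that the pipeline learns patient-robust class structure
under nuisance backgrounds — not that it would reach any particular
accuracy on real CMR data.

With `lesion_intensity = 0` the classes are exchangeable by
construction; tests use this to assert that validation accuracy falls
inside the binomial confidence band of the majority-class rate.
Class contrast is monotone in `lesion_intensity` at fixed noise, which
is asserted as a property.

## Numerical choices

* **Resampling**: bilinear, half-pixel-centre convention, edge-clamped.
  Exact on affine images (the test oracle) and idempotent at the target
  shape.
* **Normalisation**: global division by the bit-depth maximum, not
  per-image min-max, so intensity remains comparable across images —
  per-image normalisation would erase exactly the brightness signal a
  contrast lesion carries.
* **Initialisation**: Glorot-uniform with a fixed draw order; every
  CNN gets its own stream derived from (global seed, fold, CNN index),
  every tree from (forest seed, tree index).  Identical seeds reproduce
  runs bit-for-bit; the suite asserts this.
* **Epoch selection**: when a validation subset exists, the weights of
  the epoch with minimum validation loss are kept (disable with
  `select_best_epoch = FALSE`).  The baseline trains on the whole fold
  — no validation subset — and keeps final-epoch weights.
* **Split semantics**: "value ≤ threshold goes left" — half-open,
  deterministic, no double-counting of the threshold row.
* **Tie-breaks**: equal leaf counts predict the negative class; an even
  forest vote predicts the negative class.  Both are conservative
  (calling "healthy" when undecided) and irrelevant at the default 15
  trees.
* **Undefined metrics**: PPV with zero positive predictions, and
  specificity/AUC under one-class labels, are `NA` with a warning —
  never silently 0.  AUC uses mid-ranks, so ties count one half.
* **Degenerate inputs**: empty images, zero-size targets, one-class
  training sets, `n` larger than the fold, empty forests and shape
  mismatches are all rejected with specific errors rather than
  propagated as NaNs.

## Open design points and how they were resolved

* **Random-pick vs Gini-minimising splits.**  One description of the
  node rule is "a single random (row, column) pick"; the background
  convention is "minimise Gini over a √-sized feature subset".  The
  implementation draws ⌈√n⌉ random (column, sample-threshold)
  candidates and keeps the Gini-minimiser — `candidates_per_node = 1`
  recovers the fully random reading, `"all"` the exhaustive one (used
  as the oracle in tests).
* **Threshold rows: node-local.**  Thresholds are drawn from samples
  *currently in the node*; drawing from the whole fold would make deep
  nodes unsplittable (most fold values fall outside the node's range).
* **Continuous margins as features**, not hard 0/1 predictions: hard
  labels would leave trees only degenerate thresholds.
* **No pooling layers**: stride-2 convolutions already downsample; the
  architecture table lists strides and no pooling, and the minimal
  reading was adopted.
* **Patient-level folds**: fold sizes quoted per patient (~144 healthy,
  ~100 positive at the reference cohort) imply the split is by patient;
  image-level splits would leak patient backgrounds.
* **Pooled CV metrics**: per-fold confusion tables are summed, then
  metrics computed — well-defined for PPV even when a fold has no
  positive calls; per-fold reports are kept alongside.
* **Baseline AUC** uses raw margins pooled across folds.  Margins are
  not calibrated between folds, so this mildly understates the
  baseline's AUC; its accuracy, the compared quantity, is unaffected.

## Known limitations

* Binary classification only; the Gini machinery would generalise, the
  hinge head would not.
* The CNN engine is CPU-only, plain R + BLAS with two small C++
  optimizer kernels; it is sized for desk-scale cohorts (thousands of
  small images), not for 100×100 × 63k-image training runs.
* `build_feature_matrix` scores one image at a time so that the matrix
  is bit-identical to per-sample `cnn_score` calls; for large folds a
  batched variant would be faster at the cost of that guarantee.
* The reference cohort's headline accuracies are not reproduced here:
  they require the real 63,648-image dataset and long training; the
  test suite instead proves the machinery (oracle equivalences,
  invariants) and the scaled-down end-to-end behaviour, which the
  acceptance tests compute afresh on every run.
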