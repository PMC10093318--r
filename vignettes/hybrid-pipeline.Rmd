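---
title: "A hybrid texture + dense-feature pipeline for urine-sediment particle classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A hybrid texture + dense-feature pipeline for urine-sediment particle classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(urisedclass)
```

## The problem

Urine-sediment examination classifies microscopic particles — erythrocytes,
leukocytes, crystals, casts (cylinders), epithelial cells, bacteria, yeast,
plus a rare catch-all — whose counts and shapes carry diagnostic information
about renal and urinary disease. Collections of particle crops are strongly
class-imbalanced: common particles outnumber the rare catch-all by more than
thirty to one. `urisedclass` implements a hybrid pipeline for this task:
texture descriptors and dense image features are extracted per image,
independently compressed by mutual-information feature selection, fused, and
classified by classical learners.

## The texture descriptor

The Local Binary Pattern codes each interior pixel by comparing its 8
neighbours to the centre value. With the package defaults:

* **Tie rule.** A neighbour *equal* to the centre contributes a 1 bit
  (`geq_is_one`). The operator's usual informal description ("0 if less, 1 if
  larger") leaves equality open; `geq_is_one` is the standard convention and
  makes constant regions well defined (code 255, a uniform pattern). The
  strict variant `gt_is_one` is provided for sensitivity checks.
* **Bit order.** Bit 0 is the east neighbour; bits proceed counter-clockwise.
  The choice is arbitrary but must be fixed: it permutes code values without
  changing the information content of uniform-pattern histograms.
* **Border policy.** "Valid" — no padding, so an H×W image yields an
  (H−2R)×(W−2R) code map, and the cell grid is laid on the code map, not the
  image.
* **Uniform mapping.** Codes whose circular bit string has ≤ 2 transitions
  (58 of 256 for P = 8) get individual bins; all others share a catch-all,
  giving 59 bins. For general P the bin count is P(P−1)+3, which the test
  suite verifies by enumeration.
* **Cell grid.** 7 × 7 near-equal cells with boundaries at `round(k·H′/7)`,
  guaranteeing full coverage; histograms concatenate in row-major cell order
  to 59 × 49 = **2891** entries. This is the unique standard uniform-LBP
  geometry with that dimension, which is why it is the package default.

Because LBP only compares intensities, the descriptor is exactly invariant
under any strictly increasing intensity remap — a property test, and a useful
robustness guarantee against illumination and staining gain.

## The dense feature block

The second block mirrors the contract of a CNN's penultimate fully-connected
layer: image in, fixed-length dense vector out, deterministically. The
built-in backend is a handcrafted filter bank: the image is resized to
224×224 (bilinear), band-pass responses — oriented difference-of-displaced
box blurs at 4 orientations and centre-surround differences, each at 3
scales — are rectified and mean-pooled over a 4×4 grid, a DC channel keeps
per-cell mean intensity, and the 256 pooled values are projected to 1000
dimensions by a Gaussian matrix drawn once from the extractor seed. Band-pass
channels vanish exactly on constant images, so a constant raster maps to a
scalar multiple of a fixed direction — asserted in the tests.

Two design points worth making explicit:

* The backend registry exists so an adapter around a real pretrained network
  can slot in (`register_deep_backend()`); such an adapter should take
  pre-softmax activations and document its preprocessing.
* Passing the pipeline's tests with the filter-bank backend demonstrates the
  *plumbing* — shapes, determinism, fusion, selection, evaluation — and that
  the synthetic classes are separable from generic band-pass statistics. It
  does not certify accuracy figures for any pretrained network on real
  microscopy data.

## mRMR feature selection

Greedy forward selection with four criteria. Relevance is the mutual
information between the discretized feature and the class label (MID, MIQ) or
the one-way ANOVA F statistic (FCD, FCQ); redundancy against the selected set
is mean pairwise MI or mean |Pearson r|. MID/FCD subtract the mean
redundancy, MIQ/FCQ divide by it (floored at 1e-12 so the second pick is
defined). Ties break to the lowest column index, making selection fully
deterministic. The implementation keeps a running redundancy sum so each step
costs one pass over the remaining columns (the hot loop is a small C++
kernel); the tests pin its output to an exhaustive oracle that recomputes
every pairwise quantity from scratch at every step, on ≤ 12-feature
instances, for all four criteria.

Defaults: criterion MID, 10 equal-width bins per feature, k = 500 per block.
Ten bins is a conventional operating point for plug-in MI estimation at the
sample sizes involved (hundreds to thousands); the per-block k of 500 is the
pipeline's design constant — the two blocks fuse to exactly 1000 columns.

By default, selection runs once on the full feature matrix before
cross-validation. That matches the conventional order of published hybrid
pipelines but leaks label information from evaluation rows into the feature
ranking; `pipeline_config(nested_selection = TRUE)` instead reruns mRMR
inside every training fold. The default keeps comparability; the nested flag
is the honest protocol when estimating generalization.

## Classifiers and evaluation

Six classical classifiers, with hyperparameters fixed at documented defaults
rather than tuned: decision tree (Gini, `rpart`, cp = 0, depth-capped),
regularized linear discriminant (pooled covariance + 1e-6 ridge on the
diagonal, computed on standardized inputs so the ridge acts on a
correlation-like scale), Gaussian naive Bayes (variance floor 1e-9), linear
SVM (C = 1, one-vs-one), 5-NN (Euclidean), and 30 bagged trees
(bootstrap-seeded random forest with all features eligible at every split).
Standardization statistics come from the training portion only.

Evaluation offers stratified holdout (per-class train count
`floor(f·n + 0.5)`, remainder to test) and stratified k-fold CV whose pooled
out-of-fold confusion matrix spans every sample — the mode that produces
whole-dataset confusion matrices. Note that with the full 8509-image
composition the round-half-up stratified 80/20 split leaves 1702 test images
(≈ 20.0%); published protocols sometimes quote slightly different test counts
because the rounding convention is rarely stated.

Determinism choices: every fit runs under a seed derived from the classifier
seed and fold index; k-NN distance ties are resolved by the seeded RNG (ties
are measure-zero for continuous standardized features, so this choice is
unobservable in practice but keeps reruns bitwise identical).

## Metrics

Per class: recall (= per-class accuracy, correct/true), precision,
specificity, and their complements FNR, FDR, FPR, plus F1. The formatted
table *truncates* to two decimals rather than rounding — e.g. 1217/1224 =
99.428% prints as 99.42 and 30/70 = 42.857% as 42.85 — matching the
truncation convention of the reference tables this layout reproduces; all
computations upstream of formatting are full-precision. Complement identities
(recall + FNR = 100, etc.) hold exactly before formatting and are
property-tested.

## The synthetic generator

`synthetic_dataset_spec()` emulates an 8-class, class-imbalanced collection
of small textured-particle images with default counts
1224/1842/240/432/2279/1734/688/70 (total 8509, max/min ratio 2279/70),
scalable by a factor with a floor of 2 per class. Each class pairs a shape
archetype — rods (Bacteria), polygons (Crystal, Epithelial), rings
(Erythrocyte), ovals (Leukocyte, Yeast), elongated casts (Cylinder),
irregular blobs (Others) — with its own sinusoidal grating (base frequency,
orientation jitter, contrast) over speckle noise. The archetype mapping is a
caricature for testability, explicitly not a biological claim. "Others"
deliberately combines the smallest count with the most heterogeneous
generator so the benchmark reproduces, as a property, the qualitative failure
mode of rare ill-defined classes. Every image's RNG stream derives from the
master seed, the class name and the image index, so generation is
byte-deterministic and order-independent; `uniform_texture = TRUE` gives all
classes identical shape and texture parameters — a chance-level control.

What passing on this benchmark shows: the full pipeline separates
texture-distinct classes (the 50-image-per-class probe reaches ≥ 90% pooled
5-fold SVM accuracy) and collapses to chance (12.5%) when class signal is
removed. What it does not show: performance on real microscopy, where
intra-class texture variation, focus, staining and segmentation artefacts are
unmodelled.

## Problem sizes and numerical choices

The shipped tests exercise the descriptor at full 224×224 geometry, mRMR at
its full 2891 → 500 and 1000 → 500 widths (n = 400 samples for the
separability probes, n = 96 for the dimension contracts), and the
classifier harness at a few hundred samples — sizes chosen so the whole suite
completes in about a minute and a half while still covering every contract at
its production dimensions. Degenerate inputs are handled explicitly: constant
features discretize to a single bin and carry zero MI; a perfectly separating
feature returns an infinite F (sentinel, ordered first); classes never
predicted yield NA precision with a warning rather than silent zeros; classes
smaller than the fold count are a fatal error in `train_eval()` (the
`run_pipeline()` wrapper instead logs and reduces the fold count, so smoke
configurations at tiny scales remain runnable).

## Limitations

* The built-in dense extractor is a fixed filter bank; it is not a trained
  network and makes no claim of matching one. Accuracy on real data with a
  pretrained backend depends on that backend's weights and preprocessing.
* Full-matrix (non-nested) selection, the default, optimistically biases CV
  estimates; use `nested_selection = TRUE` for unbiased generalization
  estimates.
* The plug-in MI estimator with equal-width bins is biased upward at small n;
  this affects ranking only through ties in practice.
* No rotation-invariant LBP variants, multi-radius pyramids, hyperparameter
  search, probability calibration, or ROC/AUC reporting.
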