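---
title: "Classifying GAD67-positive interneurons from multichannel fluorescence crops"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying GAD67-positive interneurons from multichannel fluorescence crops}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

GABAergic interneurons are a minority of cortical neurons and are usually
identified by GAD67 immunostaining. GAD67 antibodies occupy a fluorescence
channel, add a staining step, and are exactly the label one would like to
*predict* rather than measure. `gadcell` implements a pipeline that asks: can
single neurons be classified as GAD67-positive or GAD67-negative from other
stains — a pan-neuronal nuclear marker (NeuN) and a Nissl counterstain —
whose *marginal* per-cell intensity distributions barely differ between the
two classes?

The pipeline has five stages, each usable on its own:

1. **Synthetic micrographs** (`generate_micrograph()`,
   `build_synthetic_dataset()`) — seeded multichannel z-stacks with ground
   truth, so every downstream stage is testable without the original imaging
   data.
2. **Preprocessing** (`preprocess_micrograph()` and the step functions it
   wraps) — plane selection, per-plane intensity normalization, segmentation
   mask ingestion, erosion–dilation splitting of fused regions, area
   filtering, tight crops.
3. **Dataset assembly** (`balance_downsample()`, `make_fold_plan()`,
   `select_channels()`, `make_batches()`).
4. **Classifiers** — a small fully convolutional network (`train_fcn()`) and
   a PCA + RBF-SVM baseline (`train_pca_svm()`).
5. **Evaluation** (`run_experiment()`, `compare_models()`) — per-class
   precision/recall/F1, class-size-weighted F1, 5-fold cross-validation over
   seven channel combinations, paired t-tests with Bonferroni correction.

## The classifier

The network is deliberately small: three blocks of 3×3 convolution (same
padding) → batch normalization → ReLU → dropout (rate 0.25), 2×2 max pooling
after blocks 1–2, **global max pooling**, and a 2-way softmax head. There is
no fully connected hidden layer, so the parameter count is independent of
image size and crops of any height and width are accepted — important
because cell crops are tight bounding boxes of variable size. Within a batch
of 8, crops are zero-padded bottom/right to the largest height and width in
that batch; with same-padding convolutions and ReLU before max pooling,
padded regions contribute only zeros and never win a pooling argmax against
active features.

Defaults: 16/32/64 feature maps (configurable via `fcn_spec()`), Adam with
learning rate 0.001, β₁ = 0.9, β₂ = 0.999, ε = 1e-7 (SGD with learning rate
1e-4 and momentum 0 is available), class-weighted 2-class cross-entropy,
batch size 8. Training records loss/accuracy on the training data and on a
held-aside test segment every epoch and returns the weights of the epoch
with the **lowest validation loss** (model checkpointing). Everything —
weight initialization, per-epoch batch composition, dropout — is derived
from one integer seed, and two runs with the same seed are bit-identical.

Two training details matter for stability and are worth stating:

* **Batches are re-drawn every epoch** from a fresh seeded shuffle. With
  fixed batch composition a batch-normalized network can learn features that
  depend on *which other samples share its batch*; such solutions evaluate
  arbitrarily badly under running statistics. Fresh composition each epoch
  removes that incentive.
* **Batch-norm running statistics** use momentum 0.9, so evaluation-mode
  statistics track the current weights closely even in short runs.

The loss is the sample-weighted cross-entropy; weights come from the
imbalance handling below, so the minority class is never structurally
out-voted and the softmax outputs remain interpretable as probabilities.

## Imbalance, folds, leakage

Interneurons are rare (the generator default is 15% positive). For the FCN,
the *training portion only* is balanced by randomly downsampling the
majority class to a 1:1 ratio; the retained majority samples are upweighted
by the downsampling factor, so weighted effective class counts equal the
original ones. The validation hold-out and the fold test segments are never
balanced: reported metrics reflect the natural class ratio, which is what
the class-size-weighted F1 is designed for. The SVM baseline instead trains
on the unbalanced data with balanced class weights (inverse class
frequency), which is the standard equivalent for margin classifiers.

Fold assignment is at **cell level**, not crop level: both selected z-planes
of a physical cell become separate samples but always share one fold, so a
cell can never appear in both a training and an evaluation set. 20% of cells
(floor) are held out entirely; the remaining cells form five segments of
as-equal-as-possible size. Within each fold, four segments train the model,
the fifth provides the per-epoch validation loss used for checkpointing, and
final metrics are computed on both the fold's test segment and the untouched
20% hold-out (both are emitted, labeled `test_segment` and `holdout`; the
summaries and comparisons default to the hold-out).

## Preprocessing choices

* **Planes.** The first and last plane of each z-stack are processed by
  default (`planes_used = NULL`); a single-plane stack degenerates cleanly.
* **Normalization.** Per plane and channel, an affine map sends
  `mean − SD → 0` and `mean + SD → 1` (statistics over all pixels of that
  plane). Values outside [0, 1] are *not* clipped; the output mean is
  exactly 0.5; the map is invariant to positive affine rescaling of the
  input, which removes per-plane acquisition gain. A constant plane returns
  all 0.5 with a warning.
* **Segmentation.** External masks (e.g. from a U-Net run elsewhere) pass
  through unmodified apart from relabeling to consecutive integers; binary
  masks are component-labeled first. The internal fallback — Otsu threshold
  on the NeuN channel, hole filling, labeling — exists so the pipeline runs
  without any external tool; it is a plain global threshold and is not meant
  to rival a trained segmenter.
* **Erosion–dilation splitting.** Each labeled region is eroded with a
  radius-1 *city-block* disc (diamond) until it disconnects, vanishes, or a
  10-iteration budget is spent. On disconnection each component is dilated
  back the same number of iterations and clipped to the parent region;
  pixels claimed by several children go to the nearest child (ties to the
  lower child id), keeping children disjoint. The diamond was chosen over
  the full 3×3 box deliberately: the box erodes a fused pair of round somata
  to extinction before disconnecting the waist, while the diamond severs the
  waist first. Foreground connectivity is 8-connected throughout (the
  convention of standard particle analysis); with 4-connectivity the first
  disconnection step shatters regions into diagonal fragments and fused
  pairs over-split. Intensity pixels are never modified — the algorithm
  changes region membership only.
* **Area filter.** Regions smaller than 180 px² are excluded (strict `<`:
  a region of exactly 180 px² survives), both before and after splitting —
  applying the filter once after splitting is equivalent for survivors and
  is how the pipeline composes the two steps.
* **Shape statistics.** The perimeter comes from Moore-neighbour contour
  tracing with diagonal correction (axial steps count 1, diagonal steps
  √2); circularity is `4π·area / perimeter²`. A digitized disc of radius 20
  scores ≈ 0.91; values slightly above 1 can occur for small regions and are
  reported as-is, not clipped. Mean fluorescence per ROI is taken from the
  *raw* planes; crops for learning are cut from the *normalized* planes as
  full bounding-box rectangles (not masked to the ROI).

## What the generator emulates — and what it does not

Each synthetic micrograph is a 512×512, 10-plane, 3-channel stack of
elliptical cells (area ≈ N(340, 70²) px², random orientation, soft edge
falloff, placement without overlap except for deliberately fused pairs).
Class labels are i.i.d. Bernoulli(0.15). Intensities, in arbitrary 16-bit
units, follow per-channel, per-class models:

* **GAD67 analog:** within-cell mean ~ N(11000, 1800²) for positives,
  N(4800, 1800²) for negatives — separated by ≈ 3.4 SD but overlapping, so
  mean brightness alone is informative yet imperfect.
* **NeuN and Nissl analogs:** within-cell mean ~ N(9000, 1500²) for *both*
  classes — the marginals carry no class signal. Class identity is encoded
  *jointly*: each cell has a pixel-texture field shared between the two
  channels with correlation ρ ~ N(+0.5·s, 0.35²) for positives and
  N(−0.5·s, 0.35²) for negatives, where `s` is `joint_signal_strength`
  (default 1; 0 makes the classes indistinguishable from these channels).
  A texture amplitude of 2000 units over ~300 pixels makes ρ estimable per
  cell, while the ρ distributions overlap enough that the two channels
  together support good but not perfect classification.

These levels were fixed by calibrating, once, to the relationships the
original study reports: combinations containing the GAD67 channel score
highest, NeuN+Nissl scores a few points lower, and either of those channels
alone is little better than guessing. Per-plane multiplicative gain drift
(uniform in [0.9, 1.1]) and additive Gaussian background noise (SD 400 on a
background of 800) are applied independently per plane; the per-plane
normalization is exactly the transform that removes the gain.

The generator does **not** simulate optical point-spread, photobleaching,
3-D morphology, staining chemistry, or segmentation errors beyond fused
pairs. Passing the channel-ablation experiment on this data therefore shows
that the *pipeline* — splitting, leakage-free folding, balancing, the
variable-size FCN, the metrics — behaves as designed and can exploit a
purely joint two-channel signal that defeats per-channel statistics. It does
not show that real NeuN/Nissl images contain such a signal; that evidence
lives in the original imaging study. One known divergence: the PCA-SVM
baseline does well on GAD67-bearing combinations here (~0.94 weighted F1),
because the synthetic GAD67 signal is a linearly separable brightness
difference; on real images the baseline was far weaker. The central
contrast — FCN clearly beating PCA-SVM on NeuN+Nissl, where only the joint
texture carries the class — reproduces strongly (≈ 0.90 vs ≈ 0.68, all five
folds, Bonferroni-adjusted paired t-test p < 0.05).

## Problem sizes and numerical choices

The shipped study uses six micrographs (~600 generated cells; after
splitting, area filtering and annotation ≈ 560 usable cells ≈ 1,100 crops)
and a 50-epoch training preset; `train_config()` defaults to the full 500
epochs for users who want long runs. PCA retains the minimal prefix of
components whose cumulative explained variance reaches 95%, fitted on the
training rows only; the SVM uses an RBF kernel with C = 1, balanced class
weights and `gamma = 1 / (n_dims × variance of all entries of the projected
training matrix)`. Feature rows are crops flattened row-major per channel
and zero-padded to the *training* maximum; oversize validation crops are
truncated with a warning rather than allowed to redefine the feature space.
Softmax ties predict the negative class. Undefined 0/0 metric ratios are
reported as 0 with a degeneracy flag. A paired t-test with all differences
exactly zero reports t = 0, p = 1. Bonferroni adjustment multiplies by the
number of simultaneous combination comparisons (default: those in the
report).

## Limitations

* The internal fallback segmenter is a global threshold; heavy speckle or
  uneven illumination requires an external mask source.
* Cross-plane cell linking matches ROIs by pixel overlap between planes; it
  assumes the segmentation is approximately stable across the stack, which
  holds for the generator and for slowly varying real stacks.
* Training the FCN on a CPU is practical at the shipped sizes
  (≈ 10 s per fold-combination at 50 epochs) but the full 500-epoch default
  on large datasets calls for patience.
* Occasional training runs settle into poor optima on the joint-signal task
  (visible as an early checkpoint epoch and near-chance validation
  accuracy); checkpointing and fold averaging absorb single such runs.
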