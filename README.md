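# gadcell

Classification of GAD67-positive (GABAergic) interneurons in multichannel
confocal micrographs — without using the GAD67 immunosignal.

## The problem

Cortical interneurons are routinely identified by GAD67 immunostaining, but
the GAD67 channel costs a fluorophore slot and is precisely the label one
would like to predict. Pan-neuronal stains carry subtler information: the
per-cell *marginal* intensities of a NeuN immunostain and a Nissl
counterstain barely differ between GAD67-positive and GAD67-negative
neurons, yet the *joint* pattern of the two channels can still encode cell
type. `gadcell` implements the full pipeline for testing that idea:

* a seeded **synthetic micrograph generator** (ground-truth masks and
  annotations included) emulating imbalanced two-class populations whose
  per-channel histograms overlap while class identity is recoverable from
  the joint NeuN–Nissl texture;
* **morphological preprocessing**: per-plane normalization mapping
  mean ± SD to [0, 1], erosion–dilation splitting of fused cell regions
  (raw pixels never modified), a 180 px² area filter, per-ROI
  area/perimeter/circularity and fluorescence statistics, tight crops;
* a **fully convolutional classifier**: three conv → batch-norm → ReLU →
  dropout blocks, global max pooling, softmax — no fully connected hidden
  layer, so crops of any size are accepted; trained with Adam or SGD,
  class-weighted cross-entropy and checkpointing at the minimum validation
  loss (implemented in compiled code inside the package; no external deep
  learning runtime);
* a **PCA + RBF-SVM baseline**: flatten + zero-pad, minimal ≥95%-variance
  PCA prefix fitted on training data only, C = 1, balanced class weights,
  `gamma = 1 / (n_dims × sample variance)`;
* an **evaluation harness**: per-class precision/recall/F1, the class-size
  weighted F1
  `(N₊·F1₊ + N₋·F1₋) / (N₊ + N₋)`,
  cell-level 5-fold cross-validation with a 20% hold-out, all seven channel
  combinations, paired t-tests with Bonferroni correction.

## Worked example

```r
library(gadcell)

# one synthetic 3-channel, 10-plane micrograph with ground truth
sim <- generate_micrograph(synth_config(n_cells = 100, seed = 7))
sim
#> <gad_stack> 512 x 512 px, 10 planes, channels: GAD67, NeuN, Nissl
#>   100 cells (negative: 86, positive: 14)

# segment (here: the ground-truth component mask stands in for an external
# segmenter), split fused pairs, filter, normalize, crop, annotate
cells <- preprocess_micrograph(sim$stack, masks = sim$truth$label_mask,
                               truth = sim$truth)
cells
#> <gad_cells> 194 cell images from 194 ROIs (channels: GAD67, NeuN, Nissl)

head(cells$stats[, c("roi_id", "area", "circularity",
                     "mean_GAD67", "mean_NeuN", "label")], 4)
#>   roi_id  area circularity mean_GAD67 mean_NeuN label
#> 1      1   384       0.954      7383.    11935. negative
#> 2      2   238       0.952      4012.     9030. negative
#> 3      3   399       0.903     13847.     5859. positive
#> 4      4   233       0.973      4338.    11812. negative
```

Each ROI yields one crop per selected z-plane (first and last by default).
GAD67 means differ by class (7383 and 4338 vs 13847 above) while NeuN means
overlap; area and circularity are class-independent.

The headline experiment — does the network find the class in NeuN+Nissl
where neither marginal does — on the default six-micrograph study:

```r
ds <- build_synthetic_dataset(n_stacks = 6, seed = 1)   # ~600 cells, 15% positive
rep <- run_experiment(ds, combos = list(c("NeuN", "Nissl")),
                      models = c("fcn", "pca_svm"),
                      config = train_config(epochs = 50), seed = 1)
summarize_report(rep)       # hold-out weighted F1, mean ± SD over 5 folds
#>     model      combo n  mean     sd
#> 1     fcn NeuN+Nissl 5 0.896 0.0440
#> 2 pca_svm NeuN+Nissl 5 0.679 0.0176

compare_models(rep)
#>        combo mean_fcn mean_svm fcn_wins    t  p_value
#> 1 NeuN+Nissl    0.896    0.679        5 13.8 0.000162
```

The network reaches a weighted F1 of 0.90 from the two channels whose
marginals are uninformative, beats the PCA-SVM baseline in all five folds,
and the paired t-test on fold scores is significant. `plot_ablation(rep)`,
`plot_roi_histograms(ds$stats, "mean_GAD67")` and `autoplot(fit)` (training
curves of a `train_fcn()` model) give the standard figures; `tidy()` /
`glance()` methods expose histories and fit summaries as tibbles.

A thin command-line interface with subcommands `simulate`, `preprocess`,
`train`, `baseline`, `evaluate` and `report` is installed at
`inst/cli/gadcell` (run it with `Rscript`).

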