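---
title: "Comparing transfer-learning strategies for multi-label radiograph classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing transfer-learning strategies for multi-label radiograph classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cxrtransfer)
```

## The problem

Hospitals hold modest radiograph collections (hundreds to a few thousand
studies) annotated with site-specific finding labels, while the networks that
classify such images well are trained on hundreds of thousands of images with
a different label vocabulary. `cxrtransfer` implements, at desk scale, the
standard ways of carrying a pretrained convolutional classifier over to a
small local multi-label task, so the strategies can be compared under
controlled conditions:

1. **Direct mapped inference** — run the source-trained networks unchanged
   and translate their outputs through a source-to-target label
   correspondence, taking the *maximum* source probability for each target
   label (a target finding is present if any of its source findings is).
2. **Stacked generalization** — train a random-forest metaclassifier on the
   mapped outputs of all base networks (one binary forest per target label,
   features = the full flattened classifier-by-label score matrix).
3. **Embeddings + tree classifiers** — extract each network's
   global-average-pooled (GAP) feature vector and train decision trees (DT),
   random forests (RF), or extremely randomized trees (XRT) on it, with an
   exhaustive hyperparameter grid evaluated by stratified K-fold
   cross-validated mean AUC.
4. **Fine-tuning** — replace the classification head with a fresh layer sized
   to the target labels and retrain briefly at a small learning rate.

Per-classifier probabilities $p_{k,i}$ (classifier $k$, label $i$) are
combined either by the simple average
$\tilde y_i = \frac1N \sum_{k=1}^N p_{k,i}$ or by the entropy-weighted
average $\tilde y_i = \sum_{k=1}^N (1 - H(p_{k,i}))\, p_{k,i}$, where
$H(p) = -p\log_2 p - (1-p)\log_2(1-p)$ is the binary entropy, so a maximally
uncertain vote ($p = 0.5$) contributes nothing. Performance is measured
exclusively by per-label AUROC and its unweighted mean across labels.
Saliency is assessed with Grad-CAM, masked at the 0.8 quantile, boxed, and
compared with expert masks by intersection-over-expert-area.

## Why everything runs on synthetic data

No clinical data ships with the package, and none is needed to test the
machinery: the synthetic-data module generates every input with known ground
truth.

* `synthetic_image_spec()` / `generate_images()` build grayscale images whose
  labels are *caused* by geometric signatures (disc, bar, ring segment) at
  fixed known locations, so localization claims are verifiable pixel by
  pixel. Default label names and prevalences mirror the abnormality
  frequencies of a ~941-image hospital chest-radiograph cohort (cardiac
  9.9%, lung 45.4%, pneumothorax 4.0%, pleura 14.3%, bone 14.6%, device
  15.6%). Images also receive, with small probability, a saturated
  "landmark" pixel cluster (at most 0.02% of pixels, injected at twelve
  times the image's 99th percentile) emulating the acquisition artifact that
  motivates quantile clipping.
* `synthetic_prediction_spec()` / `generate_predictions()` emulate classifier
  pools of controlled skill: a latent score $z \sim N(s\,y, 1)$ per sample
  and the exact posterior probability `plogis(s z - s^2/2)` in calibrated
  mode; an overconfident mode sharpens the logit sixfold; an uninformative
  mode emits scores near 0.5.
* `synthetic_embedding_spec()` / `generate_embeddings()` produce Gaussian
  feature matrices in which each label mean-shifts its own small set of
  informative dimensions — a stand-in for GAP embeddings with controllable
  linear signal.
* `build_fixture_cnn()` builds a small trainable CNN (3×3 same-padding
  convolutions with ReLU, 2×2 max pooling between blocks, GAP, dense sigmoid
  head) with the CAM-compatible head topology of the full-scale
  architectures it stands in for. The engine exposes probabilities, final
  conv feature maps, the GAP vector, and exact analytic gradients of any
  logit with respect to the final maps (verified against finite differences
  in the test suite).

What synthetic data does *not* show: these images have no anatomy, no
view-position or scanner variation, no label noise, and signature locations
are fixed per label. A strategy ordering observed here demonstrates that the
pipeline's machinery behaves as designed under controlled signal, not that
the same ordering holds on clinical images.

## Preprocessing

The canonical chain is **clip → scale → resize/stack → standardize**
(`preprocess_image()`), in that fixed order:

* `clip_quantile(img, q = 0.9995)` caps each pixel at the image's own
  empirical `q`-quantile, computed with linear interpolation between order
  statistics (R's default type 7). This pulls rare saturated landmark pixels
  down to background level while leaving everything below the threshold
  unchanged. One numerical subtlety: with an interpolated threshold,
  re-clipping contracts the maximum by a sliver unless the quantile lands
  exactly on an order statistic, so clipping is exactly idempotent only in
  that case and idempotent to about one part in $10^5$ otherwise.
* `scale_unit()` maps min → 0, max → 1 affinely; a constant image is
  returned as zeros with a warning.
* `resize_and_stack(img, side, crop)` optionally extracts a centered crop (a
  configurable stand-in for anatomical region extraction, whose original
  template-matching procedure is not specified here), bilinearly resizes to
  `side × side`, and replicates the result over three identical channels for
  networks expecting RGB input.
* `standardize()` subtracts and divides per-channel constants, by default
  the well-known ImageNet statistics; the fixture networks use (0.5, 0.5),
  since they are trained from scratch rather than on ImageNet-normalized
  inputs.

## Ensembling: literal versus normalized entropy weighting

The entropy-weighted average is implemented exactly as written above: the
weights $1 - H(p_{k,i})$ are *not* renormalized, so scores live in $[0, K]$
rather than $[0, 1]$. Because AUC depends only on ranking, this is harmless
for evaluation, and the literal form is the default. A normalized variant
(`entropy_weighted_average(P, normalize = TRUE)`) divides by the summed
weights, falling back to the simple average for a label whose total weight
is zero.

One property of the literal form deserves attention: $(1 - H(p))\,p$ is not
monotone in $p$ below one half (it rises from 0, peaks near $p \approx 0.22$,
and returns to 0 at $p = 0.5$). A pool of classifiers emitting confident
*negative* scores can therefore rank above a pool of weak positives, and the
literal ensemble's AUC can drop well below the simple average when base
classifiers are poorly calibrated on the target domain — visible in the
synthetic comparison report. The normalized variant restores monotonicity.
Above $p = 0.5$ the literal weighting preserves ranking, which is how the
degenerate-pool invariant is stated and tested.

## Transfer strategies: defaults and their reasons

* **Label mapping.** `map_predictions()` takes the maximum over each target
  label's source set; it is monotone (raising a source score never lowers a
  target score). `cxr_label_mapping()` ships the canonical 14-to-7 finding
  correspondence as a worked example.
* **Grid search.** `tree_grid_config()` defaults to the reference grids: max
  depth {1, 2, 3, 4, 5, 10, 20}, min samples per leaf {1, 2, 4}, min samples
  per split {2, 5, 10}, split criterion {gini, entropy}, and 10–300 trees
  for the forest variants. Every cell is enumerated and scored by stratified
  K-fold mean AUC averaged across labels (the selection criterion is this
  package's choice; K defaults to 5), ties broken by the fixed lexicographic
  order of the sorted grid so the result cannot depend on enumeration order.
  Backend note: decision trees (rpart) honor all five axes; the
  ranger-backed RF and XRT honor depth, leaf size, and tree count, but have
  no entropy split criterion and no min-samples-split analog — those axes
  are still enumerated and recorded in the CV table, just not passed
  through. XRT is ranger with `splitrule = "extratrees"`, no bootstrap, and
  full sample fraction.
* **Stacking.** One binary forest per target label (per-label AUC reporting
  and per-label class imbalance argue against a single multi-output model),
  trained on all $K \times L_t$ mapped scores; a per-label-features mode is
  available. The metaclassifier defaults to the reference selected
  hyperparameters (100 trees, depth 10, min leaf 4, gini) rather than
  re-running the full forest grid at every stacking fit; a grid config can
  be passed to search instead.
* **Fine-tuning.** `fine_tune_config()` encodes the reference protocol: five
  epochs, early stopping with patience three on validation mean AUC, binary
  cross entropy, initial learning rate $10^{-4}$ reduced tenfold after each
  epoch, and the best-validation-epoch checkpoint returned. The optimizer
  and batch size are unspecified in that protocol; the package uses an
  Adam-style adaptive optimizer and batch 16. The replacement head is
  initialized at exactly zero: at a learning rate this small the head barely
  moves in magnitude, but the very first optimizer steps point it along the
  class-difference direction of the pretrained features, and AUC depends
  only on that direction. (A random head of typical init scale would
  dominate the scores and need far more steps to wash out.) Splits are
  stratified on the rarest label's positivity; 70/10/20 by default.

## Grad-CAM and localization agreement

`grad_cam()` backpropagates the *pre-sigmoid logit* of the chosen class to
the final convolutional feature maps, spatially averages the gradient into
per-channel weights, forms the rectified weighted sum of the maps, upsamples
bilinearly to image size, and min-max normalizes to [0, 1]. For a GAP-head
network the gradient of a logit with respect to channel $c$'s map is the
constant dense weight divided by the map area, so Grad-CAM coincides with
the classical class activation map up to normalization — the package
exploits this as a correctness oracle (the two paths agree to $10^{-5}$
across random initializations). A map whose rectified sum is identically
zero (all channel contributions negative) is returned as zeros and flagged
rather than normalized.

`average_maps()` min-max normalizes each map *before* averaging, because
different networks produce gradients on incomparable scales; the mean is
then renormalized. This is used model-level (several networks, one image)
and population-level (one network, hundreds of images — the package's check
against Clever-Hans-style border shortcuts: the averaged map must be hotter
inside the designated signature region than in the border band).

`quantile_mask(map, q = 0.8)` marks pixels *strictly above* the map's own
0.8 quantile ("larger than" read literally), leaving essentially 20% of
pixels for a distinct-valued map. `bounding_box()` offers a union box or one
box per 8-connected component (components found by breadth-first flood
fill; the installed image library's labeler is 4-connected, hence the
in-package implementation). `agreement()` is intersection area over expert
area, computed on the *mask* by default — the metric is defined on areas,
and the box variant (available via `on = "box"`) can only inflate the
intersection; it is monotone in the predicted mask.

A practical observation encoded in the package's checks: localization
quality tracks optimization quality. A blob-task fixture net that only just
clears training AUC 0.95 (loss plateau around 0.12–0.19) can place its
Grad-CAM mass on background texture, while nets trained to convergence (loss
below ~0.06) recover the blob with agreement ≥ 0.5 on 90–100% of held-out
positives. The acceptance script therefore trains its localization network
for 10 epochs — to convergence at every seed probed — so the reported
agreement statistic reflects the saliency method rather than an
under-optimized network.

## The end-to-end synthetic comparison

`run_experiment()` pretrains K = 3 fixture networks of different widths
(heterogeneity standing in for the seven full-scale architectures) on a
five-label source cohort, then runs all four strategies against a
three-label target cohort whose labels are coarse unions of source findings
sharing an image region. Desk-scale problem sizes, chosen so a full run
takes about a minute on one CPU: 32×32 images, 240 source and 240 target
images, six pretraining epochs at learning rate 5×10⁻³, a reduced default
tree grid (depth {3, 10} × leaf {1, 4} × 100 trees, 3 folds). All
randomness funnels through one master seed via fixed per-stage offsets
(`child_seed()`), so a full run is bit-reproducible and every split
manifest is written to disk. Per-strategy failures are isolated and
reported in the output rather than aborting the run.

On these defaults the qualitative ordering of the strategies matches what
one expects when base classifiers degrade under domain shift while their
embeddings stay informative: trees on embeddings ≥ stacking > direct mapped
ensembling > short fine-tuning. The numbers themselves are properties of
the synthetic conditions, recomputed at run time by
`scripts/acceptance.R`; none are calibrated to any external result.

## Known limitations

* The fixture CNN engine is deliberately small (plain R matrix algebra,
  im2col convolutions); it is not a general deep-learning framework, and
  wide/deep configurations will be slow.
* The literal entropy ensemble's non-monotonicity below $p = 0.5$ (above) is
  a property of the formula, not a bug; use the normalized variant when
  calibration is poor.
* Fine-tuning at learning rate $10^{-4}$ for five decaying epochs can only
  realign the head direction; it cannot repair weak convolutional features.
  With a linear head this also bounds it by the linear separability of the
  embeddings, which the tree-based strategies do not share.
* Single-class labels (all-positive or all-negative in a split) have
  undefined AUC; they are excluded from means, skipped in fitting with a
  warning, and reported as missing.
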