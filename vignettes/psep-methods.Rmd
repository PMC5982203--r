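---
title: "Locating plant stem emerging points: models, losses and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locating plant stem emerging points: models, losses and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Cereals are sown by seed drills in narrow, semi-random rows, so seedlings
overlap heavily in top-view imagery and whole-plant segmentation cannot
separate individuals. The observable anchor of an individual plant is its
*plant stem emerging point* (PSEP): the pixel where the stem exits the soil.
Locating PSEPs gives a per-plant handle for judging seed-drill performance,
mapping emergence density across a field, and targeting per-plant treatment.

`psep` implements a complete PSEP workflow: point annotations are rasterized
into per-pixel training targets; a fully-convolutional two-class network is
trained under a penalty-weighted cross-entropy; detections are extracted from
thresholded softmax maps and scored by one-to-one point matching; and
per-image counts feed survey outputs (range classification, stratified
sampling, count regression, geo-referenced maps).

## From points to pixels: marks, halos, penalties

A human annotator marks each PSEP with a filled disk (20 px diameter at full
field resolution). `rasterize_marks()` reproduces this: pixel centers within
`mark_diameter / 2` (Euclidean, boundary inclusive) of an annotated point are
labelled 1, everything else 0, overlapping disks merging. `parse_overlay_layer()`
recovers point lists from painted red-mark layers (pure red within a
per-channel tolerance of 30/255, one point per 8-connected component
centroid).

Because the exact emergence pixel is genuinely ambiguous — annotations may be
off by a few pixels — a **non-punishing halo** surrounds each mark: a
zero-weight ring spanning radii `(mark_radius, mark_radius + halo_radius]`.
Predictions there incur no loss, so near-misses are not punished while the
marked disk still attracts the prediction. The halo radius is not dictated by
the annotation protocol; the default equals the mark radius, the smallest
scale over which annotation jitter is plausible.

**Penalty regions** encode the method's central idea. A *primary* model
trained with plain (halo-weighted) cross-entropy responds not only to true
emergence points but also to leaf tips, weeds and residue. Its false
positives, computed per training image as pixels with PSEP probability at or
above `prob_threshold` (default 0.5) lying farther than `exclusion_radius`
from every annotated point, become the penalty region for that image.
`exclusion_radius` defaults to mark radius + halo radius so that penalty,
halo and mark pixels are pairwise disjoint; keeping penalties away from true
points matters, since penalties abutting the marks punish the model for
approaching the correct location (empirically, training then fails to
converge to a useful detector). Penalty regions are derived once, from the
primary model — not re-derived every epoch.

The loss (`weighted_cross_entropy()`) is

$$E = -\frac{1}{K} \sum_{n=1}^{N} \sum_{k=1}^{K} p_n\, t_{nk} \ln y_{nk},$$

with $K = 2$ classes, one-hot targets $t_{nk}$ and per-pixel weights $p_n \in
\{0, 1, w\}$: 0 on halos, the penalty weight $w$ on penalty pixels, 1
elsewhere (including inside marks). The $1/K$ constant is reproduced exactly
under `literal_scaling = TRUE`; the training default additionally divides by
$\sum_n p_n$, which only rescales the objective (gradients point the same
way) but keeps magnitudes comparable across crop sizes. Probabilities are
clipped to $[10^{-7}, 1]$ before the logarithm. Penalty weights of 0, 50 and
75 span the model-selection grid; weights at or above 100 are known to
destabilize training when penalties sit near true points.

## The network

The segmentation architecture follows the FCN-8s pattern: a downsampling
convolutional backbone, a coarse 1×1-convolution class score at the deepest
stage, and two skip fusions in which the upsampled coarse score is summed
with 1×1 scores of shallower stages before a final upsampling to input
resolution and per-pixel softmax. Inputs of any size from 32 px per side are
accepted (replicate padding to a stride multiple, cropped after upsampling).

Two backbones share this code path:

* `"mini"` — three stages (12, 24, 32/32 channels of 3×3 convolutions, 2×2
  max pooling), fusing scores at strides 8, 4 and 2. It has a ~30 px
  receptive field, trains in minutes on one CPU, and is the backbone used by
  every example and test in this package.
* `"vgg16-fcn8s"` — the classical five-stage VGG16 topology with fusion at
  strides 32, 16 and 8, provided for full-scale work (pretrained weights are
  not bundled and are never needed by the tests).

Two implementation choices deserve a note:

* **Upsampling is nearest-neighbour.** Detection points are component
  centroids of thresholded maps, so sub-pixel smoothness of the probability
  surface buys nothing; a fixed nearest-neighbour upsampling keeps the
  adjoint trivial and exact.
* **Score layers carry no bias.** A bias on the 1×1 class-score convolutions
  gives the optimizer a single knob that shifts the PSEP logit *everywhere*.
  During penalty retraining that knob is the cheapest way to reduce the
  up-weighted penalty term, and it manifests as wholesale compression of PSEP
  probabilities — recall collapses at mid and high softmax thresholds while
  the ranking of responses barely changes. Removing the score bias closes
  this shortcut and forces the penalty gradient into feature-selective
  suppression of the actual fault responses. Backbone convolutions keep their
  biases.

Training (`fcn_train()`) is stochastic with one Adagrad update per image and
optional random square crops per epoch. The reference schedule is 40 epochs
at learning rate $10^{-3}$, halved after epochs 32 and 36, with 1500 px
crops. For the `mini` backbone trained from scratch on small synthetic
scenes, the package's studies use 12 epochs at 0.05 (drops after epochs 10
and 11 — the same 80 %/90 % positions) for the primary pass and 12 epochs at
0.01 for penalty retraining; Adagrad's accumulating denominator makes the
effective step decay quickly, so short schedules with a larger initial rate
are the natural desk-scale counterpart. All randomness (initialization,
shuffling, crops, scene synthesis) derives from explicit seeds; identical
seeds reproduce loss trajectories and predictions bit-for-bit under
fixed threading.

The retraining pass that produces the penalty-weight model family
(`train_penalty_grid()`) starts **from the primary model's parameters** for
every grid weight, including weight 0. Weight 0 nullifies the penalty term,
so the weight-0 column of the grid is simply the primary model trained for
the same total number of epochs — the penalty comparison is then free of a
training-length confound.

## Detection and evaluation

`threshold_softmax()` binarizes the PSEP channel at thresholds 0.1–0.9;
`extract_points()` groups positive pixels into 8-connected components and
returns one detection per component at the unweighted centroid (marks are
filled disks whose *center* is the intended location, so the centroid — not
the probability peak — is the natural point estimate). No minimum-area filter
is applied by default (`min_area = 1` exists for users). Note that detections
are a function of the superlevel set only; as the threshold rises components
usually merge or vanish, but a saddle between two peaks can also split one
component into two.

`match_points()` pairs detections with annotations one-to-one: among
assignments whose every pair is within the tolerance (default one mark
diameter — marks whose disks could touch), it maximizes the number of pairs,
then minimizes total distance. The optimum is computed by a Hungarian
(shortest-augmenting-path) assignment solver on a cost matrix whose
out-of-tolerance and dummy entries exceed any feasible total distance; a
greedy nearest-first pairing is *not* equivalent and is used only as a
cross-check oracle in tests, alongside brute-force enumeration. Matched
pairs are TP, unmatched detections FP, unmatched annotations FN, and

$$P = \frac{TP}{TP+FP},\qquad R = \frac{TP}{TP+FN},\qquad F = \frac{2PR}{P+R},$$

with the perfect-on-empty conventions $P = 1$ when there are no detections,
$R = 1$ when there are no annotations, and $F = 0$ when either factor is 0.
Pixel-wise accuracy is deliberately not reported: with PSEP pixels a fraction
of a percent of the image, the all-background predictor scores ~99 %.

`grid_evaluate()` sweeps penalty weights × softmax thresholds (3 × 9 = 27
cells under the reference settings), pooling TP/FP/FN over evaluation images
(micro-averaging) before computing metrics, and selects the best cell by F
with ties resolved to the lowest threshold (recall is the scarcer commodity)
and then the lowest weight. `count_regression()` reports
$R^2 = 1 - \sum(\hat y - y)^2 / \sum(y - \bar y)^2$ between predicted and
annotated counts — 1 for exact recovery, 0 for predicting the annotated mean.

## Survey outputs

Per-image counts are binned by a range scheme built from the fields' average
count: `n_steps` bins of width `average / n_steps` below and above the
average, Range 0 reserved for exactly zero, the top range open-ended. The
reference configuration (average 60, 5 steps) gives bandwidth 12 and eleven
ranges: Range 1 is (0, 12], Range 5 is (48, 60], Range 10 is (108, ∞).
Fractional bandwidths (non-integer averages) are kept unrounded; counts are
integers, so classification stays well defined. `stratified_select()` draws
up to `per_cell` images per (field, range) cell so evaluation covers sparse
and dense imagery alike — 3 fields × 11 occupied ranges × 1 = 33 images.
`augment_set()` expands annotated images fourfold (original, 90° rotation,
transpose, and the mirror their composition yields), transforming points
consistently: 212 annotated images become an evaluation pool of 848.
`render_field_map()` writes one colored marker per image position (GeoJSON +
PNG), keyed by range label under a fixed palette.

## The synthetic scene generator

Field data cannot ship with the package, so `generate_scene()` renders the
relevant structure of a top-view cereal field at desk scale:

* **soil**: a tonal base with low-frequency blotches (upsampled, smoothed
  coarse noise), per-pixel noise, and speckle clutter (pale/dark stones);
* **plants**: 2–4 anti-aliased, curved, tapering leaf strokes radiating from
  a common base pixel, with a small dark nub where the leaves meet the soil —
  the base pixel is the ground-truth PSEP; placement is uniform or along
  vertical drill rows with lateral jitter, with optional minimum spacing;
* **distractors** (diagnostic positions recorded, no truth points): weed
  rosettes — shorter, yellower leaf clusters with a fainter nub, geometrically
  emergence-like and separable mainly by hue and scale; isolated leaf-like
  strokes whose near end mimics a base; and pale residue strokes.

Sizes are scaled with the scene: 8 px marks on 128 px scenes with 8–14 px
leaves preserve the mark-to-plant ratio of 20 px marks on full-resolution
field imagery, and the matching tolerance scales likewise (8 px). Two presets
fix the study conditions: `"easy"` (no distractors, bright well-separated
plants) and `"hard"` (drill rows with overlap, extra noise, 1.2 distractors
per plant). Scenes are deterministic given their seed.

What the generator does *not* emulate: perspective and lens effects, shadows
and specular glare, real soil texture statistics, species-specific leaf
morphology, and annotation error (truth points are exact). Tests passing on
these scenes therefore demonstrate that the pipeline's machinery — losses,
penalty mechanism, matching, counting — behaves as designed, not that the
shipped `mini` model generalizes to real fields; full-scale work should
retrain the `vgg16-fcn8s` backbone on annotated field imagery.

## The desk-scale studies

Two studies, run by the test suite end-to-end on fixed seeds, mirror the
method's headline behaviours at package scale:

* **Penalty mechanism.** 100 hard 128×128 scenes (3–12 plants each) train the
  primary model; weights 0 and 75 are retrained from it; 30 held-out hard
  scenes are swept over thresholds 0.1–0.9. The expected pattern — and the
  assertion — is directional: the weight-75 model attains a strictly higher
  best-threshold F than the weight-0 model, and at the grid-selected
  operating threshold it leaves fewer false positives within one tolerance of
  a distractor site. The false-positive comparison is made at a common
  threshold because FP counts at two different operating points confound the
  training effect with the threshold choice.
* **Count recovery.** A model trained on 40 easy scenes (0–14 plants) counts
  detections (threshold 0.4) on 30 easy 384×384 scenes spanning 0–110 plants
  at matched planting density — exercising the fully-convolutional property,
  since evaluation images are nine times the training area. The assertion is
  $R^2 \ge 0.9$ between detected and true counts.

## Numerical and degenerate-input conventions

* Disk membership, halo rings and exclusion zones use pixel-center Euclidean
  distance with inclusive boundaries (`<= r`).
* Probabilities are clipped at $10^{-7}$ before logarithms; per-pixel softmax
  channels sum to 1 within $10^{-6}$.
* Empty inputs are meaningful, not errors: empty annotations give all-zero
  label masks and all-ones weight masks; empty binary maps give empty
  detection sets; empty scenes evaluate as perfect when nothing is detected.
* Matching ties (equal total distance) may pick either assignment; counts
  and total distance are unique, which is what the metrics consume.
* `stratified_select` and all generators consume explicit integer seeds; the
  package never touches the global RNG state outside `with_seed_`-style
  scoping, so library calls do not perturb user scripts.

## Known limitations

* The `mini` backbone's ~30 px receptive field bounds the plant size it can
  reason about; it is a desk-scale instrument, not a field model.
* Training is single-image Adagrad in pure R: practical for the scales above
  (seconds per epoch), not for 1500 px crops — use the full backbone with a
  GPU framework for that regime, keeping this package's masks, metrics and
  survey machinery.
* Penalty regions derive from a single primary model; iterating the
  derive-retrain loop is untested territory.
* Count regression is reported against annotated counts per image; no
  pixel-to-ground calibration is attempted, so counts are per image, not per
  square meter.
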