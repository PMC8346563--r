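---
title: "Two-stage hard-exudate localisation: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage hard-exudate localisation: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exuscan)
```

# The problem and the pipeline

Hard exudates appear in fundus photographs as compact, bright, waxy clumps,
often arranged in rings around a leakage site. Finding them matters because
their presence — and in particular their distance from the macular centre —
feeds into diabetic-retinopathy screening and macular-oedema risk. Object
detectors are expensive to run over whole high-resolution photographs, and
most 224×224 tiles of a retina contain no lesion at all. The pipeline in
this package therefore runs in two stages: a cheap linear SVM *gate*
classifies every tile as exudate-containing or not, and only the retained
tiles are passed to the object-detection stage. The gate trades a small
number of missed lesions (a higher false-negative rate) for a substantial
reduction in false positives and in detector workload.

The stages and their contracts:

* **Padding and tiling** (`pad_to_multiple()`, `tile_patches()`,
  `shifted_tiles()`): images are never resized, only padded with black rows
  and columns on the bottom/right to the next 224-multiples. Padding on
  those two sides only keeps every original pixel at its original
  coordinate, so masks and boxes never need re-registration. All
  coordinates are 0-based and half-open, so a box's width is `x1 - x0` with
  no off-by-one bookkeeping.
* **Gate** (`extract_features()`, `train_gate()`, `gate_filter()`): a
  maximum-margin linear classifier on fixed-length patch embeddings.
* **Detector** (`train_detector()`, `detect()`, `detect_image()`): a
  pluggable backend behind a single training/inference contract.
* **Evaluation** (`match_exudate_level()`, `image_level_decision()`,
  `compute_metrics()`, `aggregate_folds()`): the filled-box overlap
  protocol at the lesion level and the maximum-patch-score rule at the
  image level.

# The synthetic data generator

`generate_fundus()` renders what the downstream stages actually need to be
exercised by, not a photorealistic retina:

* a radial-gradient orange-red disc on an exactly black background, so the
  black-pixel rules (padding preservation in jitter, the 33 % black
  exclusion for SVM negatives) operate on realistic geometry;
* dark vessel arcs and a bright optic disc as confounders, so the gate and
  detector face non-trivial negatives;
* bright *streak artifacts* with lesion-range gains but high eccentricity,
  never recorded in the mask — emulating reflections and imaging
  artifacts, the classic false-positive sources a pre-scanning stage is
  meant to suppress. Without them a percentile-fit detector can learn away
  every confounder seen in training and the gate has nothing left to do,
  which does not match how these systems behave on photographs;
* soft-edged elliptical lesions whose *mask* is the crisp ellipse support,
  placed inside a random cluster circle (`cluster_frac`, default 0.3 of
  the fundus radius) because exudates cluster around leakage sites. With
  clustering, most tiles of a positive image are lesion-free — the regime
  the gate exists for. `cluster_frac = 1` spreads lesions over the whole
  disc; `separate_lesions = TRUE` (default) keeps lesion supports disjoint
  so that one lesion is one mask component, while overlapping placements
  merge into a single component, i.e. a single ground-truth object.

Default study conditions: 880×660 frames (deliberately not 224-multiples,
at reduced scale standing in for heterogeneous screening resolutions such
as 2544×1696 / 2048×1360 / 1440×960), 2–6 lesions of 3–18 px semi-axis
with additive gain 40–90 above the local background, Gaussian noise with
sigma 4, 0–2 artifacts. Datasets built by `generate_dataset()` mirror the
47-positive / 35-healthy composition through `positive_fraction`.

What passing tests on this generator do **not** show: robustness to
illumination gradients across the disc, compression artifacts, camera
colour profiles, or lesion morphologies beyond blurred ellipses
(haemorrhages, drusen and microaneurysms are out of scope). Results on
synthetic scenes bound the pipeline's logic, not its clinical accuracy.

# Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| tile | 224 | px | input size of the standard backbone |
| stride (shifted tiles) | 112 | px | half-tile offsets in x, y and both |
| `jitter max_frac` | 0.2 | fraction | 0–20 % contrast/brightness band |
| `black_threshold` | 10 | intensity (0–255) | backgrounds are near-black, not exactly 0 |
| negative:positive ratio (gate) | 2:1 | — | gate training balance |
| black-fraction cap (negatives) | 1/3 | fraction | excludes border tiles from sampling |
| pure-black patches | 4 | patches | teaches the gate the padding class |
| `overlap_min` | 0.2 | fraction of GT box area | a lesion is found only above this, strictly |
| `tau` (image level) | 0.9 | score | positive image = any patch score ≥ tau |
| `C` (gate) | 1 | — | soft-margin penalty; features are used unscaled |
| learning rate / batch / epochs | 3e-4 / 2 / 10 | — | detector training configuration |
| anchor IoU intervals | [0, 0.1) / [0.1, 1] | IoU | negative / positive anchor labelling |
| `k_folds` | 5 | — | stratified per class; 47 ids split 10/10/9/9/9, 35 split 7×5 |

The jitter band is symmetric: the stated 0–20 % magnitude is read as a gain
`g ~ U[0.8, 1.2]` about the non-black patch mean plus an offset
`b·255, b ~ U[-0.2, 0.2]`; a strictly-increasing band was the alternative
reading, but a symmetric one covers the same magnitudes and is the common
augmentation convention. Pixels at or below `black_threshold` are fixed
points for every draw, and outputs are clipped to [0, 255].

# Numerical and design choices

* **Connectivity.** Mask components use 8-connectivity by default —
  pixel-precise clinical annotations usually treat diagonal contact as one
  lesion — with 4-connectivity available. Labelling runs on the pixel
  adjacency graph (an igraph component computation); the test suite checks
  it against an independent flood-fill.
* **Overlap denominator.** The found/missed rule divides the intersection
  by the *ground-truth* filled-box area (the miss definition is written
  from the ground-truth side); dividing by the smaller of the two areas is
  available via `denominator = "min"`. The 20 % bound is strict:
  exactly 20 % is a miss.
* **Pixel bookkeeping precedence.** TP pixels are those of found
  ground-truth boxes; FN pixels those of missed ground-truth boxes minus
  TP; FP pixels those of unmatched detections minus both; everything else
  is TN. The precedence makes the four tallies a partition, so
  `sensitivity + FNR = 1` and `specificity + FPR = 1` hold to machine
  precision and the tallies always sum to the pixel count.
* **Tie at the gate boundary.** A margin of exactly zero is classified
  positive: the pre-scan should err toward sending a patch to the detector,
  since the cascade's accepted cost is extra detector work, not a missed
  lesion.
* **Mirrored patches** are generated from the original *and* shifted
  patches (the count identity 3 × (307 + 882) = 3567 pins this down), and
  when mirrored patches carry ground-truth boxes the boxes are flipped with
  the pixels.
* **Gate training patches.** The gate trains on the original + shifted
  exudate patches (the patch-division set); the mirrored and jittered
  copies are detector-training augmentation. Negatives are sampled half
  from the lesion-image background pool and half from healthy images when
  both suffice, the remainder from the larger pool — the even split is a
  package choice, as only the two sources themselves are prescribed.
* **Inference tiling** uses the base non-overlapping grid only; shifted
  tiles are a training-time augmentation. This avoids duplicate-box
  merging that the protocol never defines.
* **Fold spread** is the sample standard deviation (n − 1), sensible at
  k = 5; F1 is averaged over folds, never recomputed from averaged
  sensitivity and PPV (the two demonstrably differ).
* **Degenerate inputs.** Metrics with zero denominators are reported `NA`
  rather than 0; an empty score list is a negative image; single-class
  inputs to the gate or to ROC computation raise errors.

# The detection backends

The deep backend the configuration describes (a region-proposal detector
over a 50-layer residual backbone) is deliberately behind a contract:
`train_detector()` records the training configuration (learning rate
3·10⁻⁴, mini-batch 2, 10 epochs) and derives anchor dimensions as
quantiles of the training-box sizes, and `label_anchors()` implements the
IoU-interval anchor labelling any such backend needs. The shipped
`"reference"` backend is a deterministic contrast detector: candidate
regions are connected components of pixels whose smoothed grey intensity
exceeds the patch's non-black median by a threshold `delta`, scored by mean
contrast normalised by a `saturation` level; training fits `delta` and
`saturation` by closed-form percentiles of the lesion/background contrast
distributions (midpoint of the background 99.5th and lesion 40th
percentiles; saturation at the lesion median). It exists so the full
cascade, its bookkeeping and its evaluation are exercised end to end on one
CPU — it is a reference implementation of the *pipeline contract*, not a
substitute claim about deep-detector accuracy. An early-stopping callback
(validation error worsening five times in a row) is available to iterative
backends but defaults off; the standard runs use the fixed ten epochs.

# Problem sizes

The shipped experiments are scaled-down by design: synthetic datasets of
8–40 images at 880×660 (tests and the acceptance script), 2–5 folds, and a
per-fold cap (default 150) on the number of augmented patches used to fit
the reference detector, subsampled deterministically. These sizes were
chosen as the smallest at which every pipeline property under test is
non-trivially exercised (multi-patch grids, non-empty shifted tile sets,
satisfiable 2:1 negative sampling under the black-pixel exclusion).

# Known limitations

* The reference detector scores are contrast ratios, not calibrated
  probabilities; the 0.9 image-level threshold is used as-is, so its
  operating point on synthetic scenes differs from a trained deep
  detector's.
* The random-projection 2048-length embedding honours the backbone's
  interface and determinism but carries no learned semantics; gate accuracy
  figures on synthetic data therefore come from the closed-form extractor.
* Multi-expert fusion supports a single quorum rule (pixel marked by at
  least `ceil(quorum × n)` experts); per-expert reliability weighting is
  out of scope.
* Fold construction stratifies by image label only, not by lesion count or
  size.
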