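# exuscan

Two-stage screening and localisation of **hard exudates** — the bright,
waxy lipid deposits that are a key fundus-photography sign of diabetic
retinopathy — in full-colour retinal images. The package is aimed at
researchers building or evaluating lesion-detection pipelines: it provides
the whole chain from dataset preparation through detection to the
lesion-level and image-level evaluation protocol, plus a seeded synthetic
fundus generator so everything is testable end to end without clinical
data.

## The method

A fundus photograph is never resized. Instead it is padded with black rows
and columns to the next multiples of 224 px and tiled into 224×224
patches. Detection then runs as a cascade:

1. **SVM pre-scanning (the gate).** Each patch is mapped to a fixed-length
   feature vector by a pluggable extractor (the standard contract is the
   2048-long final average-pool embedding of a 50-layer residual network;
   a fast closed-form extractor ships for CPU work). A linear
   support-vector machine, trained with twice as many non-exudate patches
   as exudate patches (plus four pure-black patches; no sampled negative
   may exceed 33 % black pixels), discards patches judged exudate-free.
2. **Object detection.** Retained patches go to a detection backend whose
   boxes are mapped back to image coordinates. Anchor sizes are quantiles
   of the training-box dimensions; the standard training configuration is
   SGD with momentum, learning rate 3·10⁻⁴, mini-batch 2, 10 epochs, with
   anchor IoU labelling intervals [0, 0.1) negative / [0.1, 1] positive.
   A deterministic contrast-based reference backend is included so the
   pipeline logic runs on one CPU.

Training patches are augmented by half-tile (112 px) shifted grids,
mirroring along both axes (3 extra patches per input: with 307 original and
882 shifted exudate patches this yields 3 × 1189 = 3567 mirrored patches,
4756 in total), and optional 0–20 % contrast/brightness jitter that leaves
the black background untouched.

**Evaluation** follows the filled-box overlap protocol. With pixel tallies
TP/FP/FN/TN, the metrics are

    sensitivity = TP/(TP+FN)        specificity = TN/(TN+FP)
    PPV         = TP/(TP+FP)        accuracy    = (TP+TN)/total
    F1          = 2·sens·PPV/(sens+PPV)
    FPR         = FP/(FP+TN)        FNR         = FN/(FN+TP)

A ground-truth lesion counts as found when a detection box covers strictly
more than 20 % of its filled box (an any-overlap mode handles coarse
multi-expert annotations fused by a ≥ 75 % quorum). An image is called
positive when any patch score reaches 0.9. Per-fold metrics are aggregated
as mean ± sd, with F1 averaged per fold.

## Worked example

```r
library(exuscan)

# a synthetic fundus image with pixel-level ground truth
s <- generate_fundus(synth_config(seed = 3, n_lesions = c(3, 5)))
objs <- mask_to_objects(s$mask)
nrow(objs)
#> [1] 3

# tile, train the reference detector on the lesion patches, detect
padded  <- pad_to_multiple(s$image)
grid    <- label_patches(tile_patches(padded), objs)
model   <- train_detector(grid[grid$label == "exudate", ])
res     <- detect_image(s$image, model, score_threshold = 0.3)
ev      <- evaluate_image(s$mask, res$detections)
ev$metrics
#> # A tibble: 1 × 7
#>   sensitivity specificity accuracy    f1   ppv     fpr   fnr
#>         <dbl>       <dbl>    <dbl> <dbl> <dbl>   <dbl> <dbl>
#> 1           1       0.990    0.990 0.214 0.120 0.00957     0
```

Every true lesion was found (sensitivity 1, FNR 0); the low PPV reflects
false-positive pixels from bright confounders — exactly what the SVM gate
is there to remove. The gate contribution on a published five-fold
cross-validation summary:

```r
svm_contribution_report()   # FPR/FNR changes, gate on vs off, both levels
```

The full pipeline (synthesis → folds → gate → detector → evaluation →
variant report) is driven by `run_command()` / `run_pipeline()` with an
`exuscan_config()`, or from a shell via `inst/scripts/exuscan`.

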