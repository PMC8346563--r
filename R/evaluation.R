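#' Rasterise boxes into a binary image
#'
#' A pixel is on when it lies inside at least one box (the union).
#'
#' @param boxes Box tibble (0-based half-open coordinates).
#' @param shape Image shape `c(height, width)`.
#' @return Logical `H x W` matrix.
#' @export
fill_boxes <- function(boxes, shape) {
  validate_boxes(boxes)
  h <- shape[1]; w <- shape[2]
  out <- matrix(FALSE, h, w)
  if (nrow(boxes) == 0) return(out)
  if (any(boxes$x1 > w) || any(boxes$y1 > h)) {
    abort("box lies outside the image shape")
  }
  for (i in seq_len(nrow(boxes))) {
    out[(boxes$y0[i] + 1):boxes$y1[i], (boxes$x0[i] + 1):boxes$x1[i]] <- TRUE
  }
  out
}

#' Exudate-level matching of detections against ground truth
#'
#' Both ground-truth objects and detections are treated as filled
#' rectangles. In `"strict"` mode a ground-truth object counts as found when
#' some detection's box covers strictly more than `overlap_min` of the
#' ground-truth box area; in `"any_overlap"` mode (used for coarse,
#' oversized expert annotations) a single shared pixel suffices.
#'
#' Pixel bookkeeping: the pixels of found ground-truth boxes are true
#' positives; the pixels of missed ground-truth boxes are false negatives;
#' pixels of detections that qualified for no ground-truth object are false
#' positives (excluding any pixel already counted as TP or FN); everything
#' else is a true negative. The four tallies always sum to the image pixel
#' count.
#'
#' @param gt_objects Object tibble from [mask_to_objects()] (columns
#'   `component_id`, `x0`..`y1`).
#' @param detections Detection tibble (`x0`..`y1`, optionally `score`).
#' @param shape Image shape `c(height, width)`.
#' @param overlap_min Strict-mode overlap fraction that must be exceeded
#'   (default 0.2); must lie in `[0, 1)`.
#' @param mode `"strict"` or `"any_overlap"`.
#' @param denominator Overlap denominator: `"gt"` (ground-truth box area,
#'   default — the miss definition is written from the ground-truth side) or
#'   `"min"` (smaller of the two box areas).
#' @return List of class `exu_match`: `counts` (one-row tibble `tp`, `fp`,
#'   `fn`, `tn`), `gt_status` (per object: `found`, `best_overlap`),
#'   `det_status` (per detection: `matched`).
#' @export
match_exudate_level <- function(gt_objects, detections, shape,
                                overlap_min = 0.2,
                                mode = c("strict", "any_overlap"),
                                denominator = c("gt", "min")) {
  mode <- match.arg(mode)
  denominator <- match.arg(denominator)
  if (!is.numeric(overlap_min) || overlap_min < 0 || overlap_min >= 1) {
    abort("`overlap_min` must be in [0, 1)")
  }
  validate_boxes(gt_objects, "gt_objects")
  validate_boxes(detections, "detections")
  n_gt <- nrow(gt_objects); n_det <- nrow(detections)
  qualifies <- matrix(FALSE, n_gt, n_det)
  best_overlap <- rep(0, n_gt)
  if (n_gt > 0 && n_det > 0) {
    for (i in seq_len(n_gt)) {
      inter <- box_intersection_area(gt_objects[i, ], detections)
      denom <- switch(denominator,
                      gt = box_area(gt_objects[i, ]),
                      min = pmin(box_area(gt_objects[i, ]), box_area(detections)))
      frac <- inter / denom
      best_overlap[i] <- if (n_det > 0) max(frac) else 0
      qualifies[i, ] <- switch(mode,
                               strict = frac > overlap_min,
                               any_overlap = inter >= 1)
    }
  }
  found <- if (n_gt > 0) apply(qualifies, 1, any) else logical()
  matched <- if (n_det > 0 && n_gt > 0) apply(qualifies, 2, any)
             else rep(FALSE, n_det)

  tp_mask <- fill_boxes(gt_objects[found, , drop = FALSE], shape)
  fn_mask <- fill_boxes(gt_objects[!found, , drop = FALSE], shape) & !tp_mask
  fp_mask <- fill_boxes(detections[!matched, , drop = FALSE], shape) &
    !tp_mask & !fn_mask
  tp <- sum(tp_mask); fn <- sum(fn_mask); fp <- sum(fp_mask)
  tn <- prod(shape) - tp - fn - fp
  structure(list(
    counts = tibble(tp = tp, fp = fp, fn = fn, tn = tn),
    gt_status = tibble(component_id = if (n_gt) gt_objects$component_id else integer(),
                       found = found, best_overlap = best_overlap),
    det_status = tibble(detection = seq_len(n_det), matched = matched)),
    class = "exu_match")
}

#' @export
print.exu_match <- function(x, ...) {
  cat(sprintf("<exu_match> tp=%d fp=%d fn=%d tn=%d; %d/%d objects found\n",
              x$counts$tp, x$counts$fp, x$counts$fn, x$counts$tn,
              sum(x$gt_status$found), nrow(x$gt_status)))
  invisible(x)
}

#' Derived detection metrics from TP/FP/FN/TN tallies
#'
#' Computes sensitivity, specificity, accuracy, positive predictive value,
#' F1 score, false positive rate and false negative rate from the four
#' tallies. F1 is computed from sensitivity and PPV
#' (`2 * sens * ppv / (sens + ppv)`). A metric whose denominator is zero is
#' reported as `NA` (undefined).
#'
#' @param counts One-row data frame (or named vector/list) with `tp`, `fp`,
#'   `fn`, `tn`.
#' @return One-row tibble with the seven metrics.
#' @export
compute_metrics <- function(counts) {
  cl <- as.list(counts)
  tp <- cl$tp; fp <- cl$fp; fn <- cl$fn; tn <- cl$tn
  if (any(c(tp, fp, fn, tn) < 0)) abort("counts must be non-negative")
  safe <- function(num, den) if (den > 0) num / den else NA_real_
  sens <- safe(tp, tp + fn)
  spec <- safe(tn, tn + fp)
  acc <- safe(tp + tn, tp + tn + fp + fn)
  ppv <- safe(tp, tp + fp)
  f1 <- if (!is.na(sens) && !is.na(ppv) && (sens + ppv) > 0) {
    2 * sens * ppv / (sens + ppv)
  } else NA_real_
  tibble(sensitivity = sens, specificity = spec, accuracy = acc,
         f1 = f1, ppv = ppv,
         fpr = safe(fp, fp + tn), fnr = safe(fn, fn + tp))
}

#' Image-level positive/negative decision
#'
#' An image is called positive when at least one of its per-patch scores is
#' equal to or higher than `tau` (default 0.9). An image with no scores is
#' negative.
#'
#' @param per_patch_scores Numeric vector of per-patch scores in `[0, 1]`
#'   (typically the maximum detection confidence per patch).
#' @param tau Decision threshold.
#' @return Logical scalar.
#' @export
image_level_decision <- function(per_patch_scores, tau = 0.9) {
  stop_if_not_scalar_frac(tau, "tau")
  if (length(per_patch_scores) == 0) return(FALSE)
  if (any(per_patch_scores < 0 | per_patch_scores > 1)) {
    abort("per-patch scores must lie in [0, 1]")
  }
  max(per_patch_scores) >= tau
}

#' Image-level confusion metrics
#'
#' Tallies are image counts rather than pixels; the same metric formulas
#' apply.
#'
#' @param decisions Logical vector of per-image positive calls.
#' @param labels Logical vector of per-image ground-truth labels.
#' @return One-row tibble of metrics (see [compute_metrics()]).
#' @export
image_level_metrics <- function(decisions, labels) {
  if (length(decisions) == 0) abort("no images to evaluate")
  if (length(decisions) != length(labels)) abort("lengths differ")
  d <- as.logical(decisions); l <- as.logical(labels)
  compute_metrics(list(tp = sum(d & l), fp = sum(d & !l),
                       fn = sum(!d & l), tn = sum(!d & !l)))
}

#' Area under the ROC curve
#'
#' The AUC is the probability that a randomly chosen positive image scores
#' higher than a randomly chosen negative one, with ties counted one half —
#' equivalently the trapezoidal area under the ROC sweep.
#'
#' @param scores Numeric image scores.
#' @param labels Logical (or 0/1) image labels; both classes must be
#'   present.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  l <- as.logical(labels)
  if (length(scores) != length(l)) abort("lengths differ")
  n_pos <- sum(l); n_neg <- sum(!l)
  if (n_pos == 0 || n_neg == 0) abort("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[l]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' ROC curve points
#'
#' @inheritParams roc_auc
#' @return Tibble with `threshold`, `fpr`, `tpr`, swept over the observed
#'   score values (plus sentinels), suitable for plotting.
#' @export
roc_points <- function(scores, labels) {
  l <- as.logical(labels)
  thr <- sort(unique(c(-Inf, scores, Inf)), decreasing = TRUE)
  list_rbind(map(thr, function(t) {
    d <- scores >= t
    tibble(threshold = t,
           fpr = if (sum(!l) > 0) sum(d & !l) / sum(!l) else 0,
           tpr = if (sum(l) > 0) sum(d & l) / sum(l) else 0)
  }))
}

#' Relative change between two rates, in percent
#'
#' Returns `100 * (after - before) / before`; negative values are
#' reductions. Used to quantify the contribution of the SVM gate to the
#' false positive and false negative rates.
#'
#' @param before,after Rates; `before` must be positive.
#' @return Signed percent change.
#' @examples
#' relative_change(0.0037, 0.0026)  # -29.7: a 29.7% FPR reduction
#' @export
relative_change <- function(before, after) {
  if (!is.numeric(before) || any(before <= 0)) abort("`before` must be positive")
  100 * (after - before) / before
}

#' Aggregate per-fold metrics as mean and standard deviation
#'
#' Each metric is averaged over folds; in particular F1 is the mean of the
#' per-fold F1 values, not F1 recomputed from the averaged sensitivity and
#' PPV (the two generally differ). The spread is the sample standard
#' deviation (n - 1 denominator; `NA` for a single fold).
#'
#' @param fold_metrics Tibble with one row per fold (metric columns as from
#'   [compute_metrics()], plus optionally a `fold` id column which is
#'   ignored).
#' @return Tibble with columns `metric`, `mean`, `sd`.
#' @export
aggregate_folds <- function(fold_metrics) {
  if (nrow(fold_metrics) == 0) abort("no folds to aggregate")
  m <- fold_metrics[, setdiff(names(fold_metrics), c("fold", "variant", "level")),
                    drop = FALSE]
  tidyr::pivot_longer(m, dplyr::everything(), names_to = "metric") |>
    group_by(.data$metric) |>
    summarise(mean = mean(.data$value, na.rm = TRUE),
              sd = stats::sd(.data$value), .groups = "drop") |>
    dplyr::slice(match(names(m), .data$metric))
}

#' Evaluate detections for one image at the exudate level
#'
#' Convenience wrapper: extracts ground-truth objects from the mask, runs
#' [match_exudate_level()] against the detections, and computes the metric
#' set.
#'
#' @param mask Binary ground-truth mask.
#' @param detections Detection tibble in image coordinates.
#' @param overlap_min,mode Passed to [match_exudate_level()].
#' @return List with `counts`, `metrics`, `match`.
#' @export
evaluate_image <- function(mask, detections, overlap_min = 0.2,
                           mode = "strict") {
  objs <- mask_to_objects(mask)
  m <- match_exudate_level(objs, detections, dim(mask),
                           overlap_min = overlap_min, mode = mode)
  list(counts = m$counts, metrics = compute_metrics(m$counts), match = m)
}
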