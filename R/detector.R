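#' Detector training configuration
#'
#' Holds the object-detector training hyper-parameters. Defaults follow the
#' standard configuration for this pipeline: stochastic gradient descent
#' with momentum, learning rate 3e-4, mini-batch 2, ten epochs, and region
#' proposal anchor labelling intervals `[0, 0.1)` (negative) / `[0.1, 1]`
#' (positive) on the anchor-to-ground-truth IoU.
#'
#' @param learning_rate Fixed learning rate.
#' @param mini_batch Mini-batch size.
#' @param epochs Number of training epochs (`>= 1`).
#' @param negative_overlap,positive_overlap IoU intervals `c(lo, hi)` used
#'   to label anchors negative / positive; the negative upper bound must not
#'   exceed the positive lower bound.
#' @param anchor_dims Optional tibble of anchor `(w, h)` sizes; derived from
#'   the training boxes when `NULL`.
#' @param backend_id Backend identifier; `"reference"` is the built-in
#'   deterministic contrast-based detector.
#' @return An `exu_detector_config`.
#' @export
detector_config <- function(learning_rate = 3e-4, mini_batch = 2,
                            epochs = 10,
                            negative_overlap = c(0, 0.1),
                            positive_overlap = c(0.1, 1),
                            anchor_dims = NULL,
                            backend_id = "reference") {
  cfg <- list(learning_rate = learning_rate, mini_batch = as.integer(mini_batch),
              epochs = as.integer(epochs),
              negative_overlap = as.numeric(negative_overlap),
              positive_overlap = as.numeric(positive_overlap),
              anchor_dims = anchor_dims, backend_id = backend_id)
  if (cfg$epochs < 1) abort("`epochs` must be at least 1")
  no <- cfg$negative_overlap; po <- cfg$positive_overlap
  if (length(no) != 2 || length(po) != 2 || no[1] < 0 || po[2] > 1 ||
      no[2] > po[1]) {
    abort("overlap intervals must satisfy 0 <= negative hi <= positive lo <= 1")
  }
  class(cfg) <- "exu_detector_config"
  cfg
}

#' Derive anchor box dimensions from training box sizes
#'
#' Anchor widths and heights are quantiles of the training-box width and
#' height distributions at equally spaced probability levels, so anchors
#' track the sizes of the objects actually present in the training set.
#'
#' @param boxes Box tibble of training objects.
#' @param n_anchors Number of anchors (`>= 1`; a single anchor uses the
#'   median).
#' @return Tibble with columns `w` and `h`, each at least 1 pixel; invariant
#'   to the order of `boxes`.
#' @export
derive_anchors <- function(boxes, n_anchors = 5) {
  validate_boxes(boxes)
  if (nrow(boxes) == 0) abort("cannot derive anchors from an empty box list")
  if (n_anchors < 1) abort("`n_anchors` must be at least 1")
  probs <- if (n_anchors == 1) 0.5 else seq(0, 1, length.out = n_anchors)
  w <- pmax(1, round(as.numeric(quantile(boxes$x1 - boxes$x0, probs))))
  h <- pmax(1, round(as.numeric(quantile(boxes$y1 - boxes$y0, probs))))
  tibble(w = w, h = h)
}

#' Label anchors against ground truth by IoU intervals
#'
#' Each anchor box takes its maximum IoU over the ground-truth boxes and is
#' labelled `"positive"` when that IoU falls in `positive_overlap`
#' (inclusive), `"negative"` when it falls in `[negative lo, negative hi)`,
#' and `"ignored"` otherwise.
#'
#' @param anchor_boxes,gt_boxes Box tibbles.
#' @param negative_overlap,positive_overlap IoU intervals as in
#'   [detector_config()].
#' @return Tibble with `max_iou` and `label` per anchor.
#' @export
label_anchors <- function(anchor_boxes, gt_boxes,
                          negative_overlap = c(0, 0.1),
                          positive_overlap = c(0.1, 1)) {
  validate_boxes(anchor_boxes, "anchor_boxes")
  validate_boxes(gt_boxes, "gt_boxes")
  max_iou <- if (nrow(gt_boxes) == 0) rep(0, nrow(anchor_boxes)) else {
    map_dbl(seq_len(nrow(anchor_boxes)),
            function(i) max(box_iou(anchor_boxes[i, ], gt_boxes)))
  }
  label <- ifelse(max_iou >= positive_overlap[1] & max_iou <= positive_overlap[2],
                  "positive",
                  ifelse(max_iou >= negative_overlap[1] & max_iou < negative_overlap[2],
                         "negative", "ignored"))
  tibble(max_iou = max_iou, label = label)
}

#' Train the object-detection stage
#'
#' Training patches must each contain at least one ground-truth box — the
#' detector trains on lesion-containing patches only. Anchor dimensions are
#' derived from the training boxes unless supplied in the config.
#'
#' The built-in `"reference"` backend is a deterministic contrast detector:
#' training fits, by closed-form percentiles, the contrast threshold
#' separating lesion pixels from background pixels and the contrast level at
#' which the confidence score saturates. It requires no gradient descent and
#' no GPU, so the full pipeline is testable on one CPU; the epoch /
#' learning-rate / batch settings are recorded in the model metadata for any
#' iterative backend plugged in through the same contract.
#'
#' @param patches Patch tibble with a `boxes` list-column of patch-local
#'   ground-truth boxes (see [label_patches()]).
#' @param config An [detector_config()].
#' @param black_threshold Intensity at or below which pixels are treated as
#'   background padding.
#' @return An `exu_detector` model.
#' @export
train_detector <- function(patches, config = detector_config(),
                           black_threshold = 10) {
  stopifnot(inherits(config, "exu_detector_config"))
  if (nrow(patches) == 0) abort("no training patches supplied")
  if (!"boxes" %in% names(patches)) abort("training patches need a `boxes` column")
  n_boxes <- map_int(patches$boxes, nrow)
  if (any(n_boxes == 0)) {
    abort(sprintf("training patches without ground-truth boxes are not allowed (rows: %s)",
                  paste(which(n_boxes == 0), collapse = ", ")))
  }
  all_boxes <- list_rbind(patches$boxes)
  anchors <- config$anchor_dims %||% derive_anchors(all_boxes,
                                                    n_anchors = min(5, nrow(all_boxes)))
  # closed-form percentile fit of the contrast threshold
  lesion_contrast <- c(); background_contrast <- c()
  for (i in seq_len(nrow(patches))) {
    px <- patches$pixels[[i]]
    g <- gray_intensity(px)
    nonblack <- channel_max(px) > black_threshold
    if (!any(nonblack)) next
    bg_med <- median(g[nonblack])
    inb <- fill_boxes(patches$boxes[[i]], dim(g))
    lesion_contrast <- c(lesion_contrast, g[inb & nonblack] - bg_med)
    background_contrast <- c(background_contrast, g[!inb & nonblack] - bg_med)
  }
  if (length(lesion_contrast) == 0) abort("no lesion pixels found in training patches")
  hi_bg <- as.numeric(quantile(background_contrast, 0.995))
  lo_les <- as.numeric(quantile(lesion_contrast, 0.40))
  delta <- max(5, (hi_bg + lo_les) / 2)
  saturation <- max(delta * 1.2, as.numeric(quantile(lesion_contrast, 0.50)))
  structure(list(backend = config$backend_id,
                 params = list(delta = delta, saturation = saturation,
                               min_area = 4L, black_threshold = black_threshold),
                 anchors = anchors, config = config, trained = TRUE,
                 n_training_patches = nrow(patches)),
            class = "exu_detector")
}

#' @export
print.exu_detector <- function(x, ...) {
  cat(sprintf("<exu_detector> backend=%s, delta=%.1f, saturation=%.1f, %d anchors\n",
              x$backend, x$params$delta, x$params$saturation, nrow(x$anchors)))
  invisible(x)
}

#' Early-stopping monitor for iterative detector backends
#'
#' Returns a stateful monitor for use inside a training loop: feed it the
#' validation error after each epoch and it reports whether training should
#' stop because the error has worsened `patience` times in a row. The
#' standard training runs use a fixed epoch count with no early stop; the
#' monitor is the optional alternative for backends that iterate.
#'
#' @param patience Number of consecutive worsenings that triggers a stop
#'   (default 5).
#' @return A function `f(validation_error)` returning `TRUE` when training
#'   should stop.
#' @examples
#' stop_now <- early_stopping(patience = 2)
#' stop_now(1.0); stop_now(1.1)  # worse once
#' stop_now(1.2)                 # worse twice -> TRUE
#' @export
early_stopping <- function(patience = 5) {
  stopifnot(patience >= 1)
  last <- Inf
  worse <- 0L
  function(validation_error) {
    if (validation_error > last) {
      worse <<- worse + 1L
    } else {
      worse <<- 0L
    }
    last <<- validation_error
    worse >= patience
  }
}

#' Deterministic contrast-based region detector
#'
#' Candidate regions are the connected components of pixels whose smoothed
#' grey intensity exceeds the patch background (median of non-black pixels)
#' by more than `delta`. Each component of at least `min_area` pixels yields
#' one detection whose box is the component's tight bound and whose score is
#' the component's mean contrast normalised by `saturation`, clipped to
#' `[0, 1]`. The operation is fully deterministic.
#'
#' @param pixels Patch pixel array.
#' @param params List with `delta`, `saturation`, `min_area`,
#'   `black_threshold`.
#' @return Detection tibble (`x0`, `y0`, `x1`, `y1`, `score`) sorted by
#'   descending score.
#' @export
reference_detect <- function(pixels, params) {
  validate_image(pixels, "pixels")
  g <- box_blur3(gray_intensity(pixels))
  nonblack <- channel_max(pixels) > params$black_threshold
  empty <- tibble(x0 = numeric(), y0 = numeric(), x1 = numeric(),
                  y1 = numeric(), score = numeric())
  if (!any(nonblack)) return(empty)
  bg_med <- median(g[nonblack])
  excess <- g - bg_med
  cand <- (excess > params$delta) & nonblack
  if (!any(cand)) return(empty)
  objs <- mask_to_objects(cand * 1L, connectivity = 8)
  labels <- mask_components(cand * 1L, connectivity = 8)
  objs <- objs[objs$pixel_count >= params$min_area, ]
  if (nrow(objs) == 0) return(empty)
  score <- map_dbl(objs$component_id, function(id) {
    mean_excess <- mean(excess[labels == id])
    min(1, max(0, mean_excess / params$saturation))
  })
  out <- tibble(x0 = objs$x0, y0 = objs$y0, x1 = objs$x1, y1 = objs$y1,
                score = score)
  arrange(out, dplyr::desc(.data$score))
}

#' Run the detector on a single patch
#'
#' @param model A trained `exu_detector`.
#' @param patch One-row patch tibble or a pixel array.
#' @param score_threshold Minimum confidence to report, in `[0, 1]`.
#' @return Detection tibble sorted by descending score; boxes lie within
#'   the patch bounds.
#' @export
detect <- function(model, patch, score_threshold = 0.5) {
  stopifnot(inherits(model, "exu_detector"))
  if (!isTRUE(model$trained)) abort("the detector model is not trained")
  if (!is.numeric(score_threshold) || score_threshold < 0 || score_threshold > 1) {
    abort("`score_threshold` must be in [0, 1]")
  }
  px <- if (is.data.frame(patch)) patch$pixels[[1]] else patch
  if (dim(px)[1] != 224 || dim(px)[2] != 224) abort("patches must be 224 x 224 x 3")
  if (model$backend != "reference") {
    abort(sprintf("backend '%s' is not available in this installation", model$backend))
  }
  det <- reference_detect(px, model$params)
  det[det$score >= score_threshold, ]
}

#' Detect exudates on a full image
#'
#' Composes the whole inference pipeline: pad the image to a tile multiple,
#' tile it with the base non-overlapping grid, optionally discard patches
#' with the SVM gate, run the detector on the retained patches, and map the
#' boxes back to image coordinates. Shifted tiles are a training-time
#' augmentation and are not used at inference.
#'
#' @param image `H x W x 3` array.
#' @param model Trained `exu_detector`.
#' @param gate Optional `exu_gate` (requires `extractor`), or a custom
#'   predicate `function(patches)` returning one logical per patch row —
#'   useful for oracle-gate experiments.
#' @param extractor `exu_extractor` for the gate.
#' @param score_threshold Detection confidence threshold.
#' @param source_id Image identifier carried through the manifests.
#' @return List of class `exu_image_result` with `detections` (image
#'   coordinates, clipped to the original image bounds) and
#'   `per_patch_scores`: one row per grid patch with its origin, whether the
#'   gate retained it, and the maximum detection score (0 when gated out or
#'   detection-free).
#' @export
detect_image <- function(image, model, gate = NULL, extractor = NULL,
                         score_threshold = 0.5, source_id = "image") {
  validate_image(image)
  padded <- pad_to_multiple(image)
  grid <- tile_patches(padded, source_id = source_id)
  retained <- if (is.function(gate)) {
    as.logical(gate(grid))
  } else if (!is.null(gate)) {
    if (is.null(extractor)) abort("`extractor` is required when a gate is supplied")
    kept <- gate_filter(grid, gate, extractor)
    paste(grid$origin_x, grid$origin_y) %in% paste(kept$origin_x, kept$origin_y)
  } else rep(TRUE, nrow(grid))
  w0 <- padded$original_size[["width"]]; h0 <- padded$original_size[["height"]]
  dets <- list(); max_score <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    if (!retained[i]) next
    d <- detect(model, grid[i, ], score_threshold)
    if (nrow(d) == 0) next
    max_score[i] <- max(d$score)
    dd <- to_image_coords(d[, c("x0", "y0", "x1", "y1")], grid[i, ])
    dd$score <- d$score
    # clip to the original (pre-padding) image bounds
    dd$x1 <- pmin(dd$x1, w0); dd$y1 <- pmin(dd$y1, h0)
    dd <- dd[dd$x1 > dd$x0 & dd$y1 > dd$y0, ]
    dets[[length(dets) + 1]] <- dd
  }
  detections <- if (length(dets)) list_rbind(dets) else
    tibble(x0 = numeric(), y0 = numeric(), x1 = numeric(), y1 = numeric(),
           score = numeric())
  structure(list(
    detections = arrange(detections, dplyr::desc(.data$score)),
    per_patch_scores = tibble(source_id = source_id,
                              origin_x = grid$origin_x,
                              origin_y = grid$origin_y,
                              retained = retained,
                              max_score = max_score),
    original_size = padded$original_size),
    class = "exu_image_result")
}

#' @export
print.exu_image_result <- function(x, ...) {
  cat(sprintf("<exu_image_result> %d detection(s) over %d patches (%d retained)\n",
              nrow(x$detections), nrow(x$per_patch_scores),
              sum(x$per_patch_scores$retained)))
  invisible(x)
}
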