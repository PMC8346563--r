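#' Pipeline run configuration
#'
#' Aggregates every stage's tunables into one object that the staged
#' commands ([run_command()]) and the end-to-end runner ([run_pipeline()])
#' consume. All stage seeds are derived from the single `seed`, so a run is
#' reproducible end to end while stages stay reproducible in isolation.
#'
#' @param output_dir Directory for all artifacts.
#' @param n_images,positive_fraction Synthetic dataset size and class mix.
#' @param synth [synth_config()] for the generator (its `seed` is
#'   overridden by the derived stage seed).
#' @param tile,stride Patch tiling parameters (224 / 112).
#' @param use_jitter Apply contrast-jitter augmentation to the detector
#'   training patches (the "contrast adjustment" variant switch).
#' @param jitter_max_frac Jitter band half-width.
#' @param black_threshold Black-pixel intensity cutoff shared by the
#'   augmentation, the SVM set rules and the detector.
#' @param use_gate Enable SVM pre-scanning at inference (the "+SVM" variant
#'   switch).
#' @param extractor `exu_extractor` for the gate (default [toy_extractor()]).
#' @param svm_C Gate soft-margin penalty.
#' @param detector [detector_config()].
#' @param score_threshold Detection confidence threshold at inference.
#' @param overlap_min,match_mode Exudate-level matching parameters.
#' @param tau Image-level decision threshold.
#' @param k_folds Cross-validation folds.
#' @param detector_patch_cap Maximum number of (augmented) patches used to
#'   fit the detector per fold; a deterministic subsample keeps memory and
#'   runtime bounded at small scale.
#' @param seed Global integer seed.
#' @return An `exuscan_config`.
#' @export
exuscan_config <- function(output_dir = tempfile("exuscan_run_"),
                           n_images = 20, positive_fraction = 0.5,
                           synth = synth_config(),
                           tile = 224, stride = 112,
                           use_jitter = TRUE, jitter_max_frac = 0.2,
                           black_threshold = 10,
                           use_gate = TRUE, extractor = toy_extractor(),
                           svm_C = 1,
                           detector = detector_config(),
                           score_threshold = 0.5,
                           overlap_min = 0.2, match_mode = "strict",
                           tau = 0.9, k_folds = 5,
                           detector_patch_cap = 150,
                           seed = 1L) {
  cfg <- list(output_dir = output_dir, n_images = n_images,
              positive_fraction = positive_fraction, synth = synth,
              tile = tile, stride = stride, use_jitter = use_jitter,
              jitter_max_frac = jitter_max_frac,
              black_threshold = black_threshold, use_gate = use_gate,
              extractor = extractor, svm_C = svm_C, detector = detector,
              score_threshold = score_threshold, overlap_min = overlap_min,
              match_mode = match_mode, tau = tau, k_folds = k_folds,
              detector_patch_cap = detector_patch_cap,
              seed = as.integer(seed))
  class(cfg) <- "exuscan_config"
  cfg
}

#' Read or write a pipeline configuration as YAML
#'
#' The extractor and detector config are stored by id/fields and rebuilt on
#' read.
#'
#' @param path YAML file path.
#' @return `read_run_config()` returns an `exuscan_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  y$synth <- do.call(synth_config, y$synth)
  y$detector <- do.call(detector_config, y$detector)
  y$extractor <- if (identical(y$extractor, "toy")) toy_extractor()
                 else pooled_embedding_extractor()
  do.call(exuscan_config, y)
}

#' @rdname read_run_config
#' @param config An `exuscan_config`.
#' @export
write_run_config <- function(config, path) {
  y <- unclass(config)
  y$synth <- unclass(y$synth)
  y$detector <- unclass(y$detector)
  y$detector$anchor_dims <- NULL
  y$extractor <- if (grepl("^toy", config$extractor$id)) "toy" else "pooled"
  yaml::write_yaml(y, path)
  invisible(path)
}

pipe_paths <- function(config) {
  d <- config$output_dir
  list(dir = d, data = file.path(d, "data"),
       manifest = file.path(d, "data", "manifest.csv"),
       folds = file.path(d, "folds.csv"),
       patches = file.path(d, "patches.csv"),
       svm_sets = file.path(d, "svm_sets.csv"),
       gates = file.path(d, "gates.json"),
       detectors = file.path(d, "detectors.json"),
       detections = file.path(d, "detections.csv"),
       patch_scores = file.path(d, "patch_scores.csv"),
       evaluation = file.path(d, "evaluation.json"),
       report_csv = file.path(d, "report.csv"),
       report_deltas = file.path(d, "report_deltas.csv"),
       log = file.path(d, "run_log.json"))
}

require_artifact <- function(path, stage) {
  if (!file.exists(path)) {
    abort(sprintf("stage '%s' requires missing artifact '%s'", stage, path))
  }
  invisible(path)
}

append_log <- function(config, stage, info) {
  p <- pipe_paths(config)
  entry <- c(list(stage = stage, seed = config$seed,
                  config_hash = rlang::hash(write_run_config_string(config)),
                  timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
             info)
  log <- if (file.exists(p$log)) jsonlite::read_json(p$log) else list()
  log[[length(log) + 1]] <- entry
  jsonlite::write_json(log, p$log, auto_unbox = TRUE, pretty = TRUE)
  invisible(entry)
}

write_run_config_string <- function(config) {
  y <- unclass(config)
  y$synth <- unclass(y$synth); y$detector <- unclass(y$detector)
  y$extractor <- config$extractor$id
  yaml::as.yaml(y)
}

load_sample <- function(row) {
  list(image = read_image_png(row$image_path),
       mask = read_image_png(row$mask_path, mask = TRUE),
       label = row$label == "exudates")
}

# Flip patch-local boxes to match a pixel flip.
flip_boxes <- function(boxes, tile, horizontal, vertical) {
  if (nrow(boxes) == 0) return(boxes)
  out <- boxes
  if (horizontal) {
    out$x0 <- tile - boxes$x1; out$x1 <- tile - boxes$x0
  }
  if (vertical) {
    tmp0 <- out$y0; tmp1 <- out$y1
    out$y0 <- tile - tmp1; out$y1 <- tile - tmp0
  }
  out
}

# Mirror labelled patches, flipping their ground-truth boxes along with the
# pixels. mirror_patches() emits three blocks (h, v, hv) of nrow(patches).
mirror_with_boxes <- function(patches, tile = 224) {
  m <- mirror_patches(patches)
  n <- nrow(patches)
  flips <- list(c(TRUE, FALSE), c(FALSE, TRUE), c(TRUE, TRUE))
  for (blk in 1:3) {
    idx <- ((blk - 1) * n + 1):(blk * n)
    m$boxes[idx] <- map(patches$boxes, flip_boxes, tile = tile,
                        horizontal = flips[[blk]][1],
                        vertical = flips[[blk]][2])
  }
  m
}

# Build, for one image, the labelled base grid, the labelled shifted tiles,
# and the augmented positive training set (originals + shifted + mirrored,
# plus jittered copies when requested).
prepare_image <- function(sample, config, source_id, jitter_seed = NULL) {
  padded <- pad_to_multiple(sample$image, config$tile)
  objects <- mask_to_objects(sample$mask)
  grid <- label_patches(tile_patches(padded, source_id), objects, config$tile)
  shifted <- label_patches(shifted_tiles(padded, config$stride, source_id),
                           objects, config$tile)
  pos <- bind_rows(grid[grid$label == "exudate", ],
                   shifted[shifted$label == "exudate", ])
  train_pos <- if (nrow(pos) > 0) bind_rows(pos, mirror_with_boxes(pos, config$tile))
               else pos
  if (isTRUE(config$use_jitter) && nrow(train_pos) > 0) {
    jit <- jitter_patches(train_pos, config$jitter_max_frac,
                          config$black_threshold, seed = jitter_seed)
    jit$boxes <- train_pos$boxes  # intensity-only transform
    train_pos <- bind_rows(train_pos, jit)
  }
  list(grid = grid, shifted = shifted, pos = pos, train_pos = train_pos,
       objects = objects)
}

# Gather the per-fold training material: gate features/labels and a capped
# detector training set. The gate trains on the original + shifted exudate
# patches (the patch-division set), with negatives sampled 2:1 under the
# black-pixel exclusion plus the four pure-black patches; the detector
# additionally gets the mirrored (and optionally jittered) copies.
gather_fold_training <- function(manifest, folds, hold_out, config) {
  train_ids <- folds$image_id[folds$fold != hold_out]
  rows <- manifest[manifest$image_id %in% train_ids, ]
  ex <- config$extractor
  pos_feat <- list(); neg_dr <- list(); neg_healthy <- list()
  det_patches <- list()
  for (i in seq_len(nrow(rows))) {
    s <- load_sample(rows[i, ])
    prep <- prepare_image(s, config, rows$image_id[i],
                          jitter_seed = derive_seed(config$seed,
                                                    paste0("jit", rows$image_id[i])))
    if (nrow(prep$train_pos) > 0) {
      pos_feat[[length(pos_feat) + 1]] <- extract_features(prep$pos, ex)
      det_patches[[length(det_patches) + 1]] <-
        prep$train_pos[, c("source_id", "origin_x", "origin_y", "provenance",
                           "pixels", "boxes")]
    }
    negs <- bind_rows(prep$grid[prep$grid$label == "non_exudate", ],
                      prep$shifted[prep$shifted$label == "non_exudate", ])
    if (nrow(negs) > 0) {
      if (s$label) neg_dr[[length(neg_dr) + 1]] <- negs
      else neg_healthy[[length(neg_healthy) + 1]] <- negs
    }
  }
  det_patches <- if (length(det_patches)) list_rbind(det_patches) else NULL
  if (!is.null(det_patches) && nrow(det_patches) > config$detector_patch_cap) {
    keep <- with_seed(derive_seed(config$seed, paste0("detcap", hold_out)),
                      sample.int(nrow(det_patches), config$detector_patch_cap))
    det_patches <- det_patches[sort(keep), ]
  }
  n_pos <- sum(map_int(pos_feat, nrow))
  svm <- NULL
  if (n_pos > 0) {
    neg_dr_tbl <- if (length(neg_dr)) list_rbind(neg_dr) else
      new_patch_tbl(list(), integer(), integer(), character(), character())
    neg_he_tbl <- if (length(neg_healthy)) list_rbind(neg_healthy) else
      new_patch_tbl(list(), integer(), integer(), character(), character())
    svm_negs <- sample_svm_negatives(neg_dr_tbl, neg_he_tbl, 2L * n_pos,
                                     config$black_threshold,
                                     seed = derive_seed(config$seed,
                                                        paste0("svmneg", hold_out)))
    black_px <- array(0, dim = c(config$tile, config$tile, 3))
    neg_feat <- rbind(
      if (nrow(svm_negs) > 0) extract_features(svm_negs, ex),
      extract_features(new_patch_tbl(rep(list(black_px), 4), rep(0L, 4),
                                     rep(0L, 4), "black", "black"), ex))
    svm <- list(features = rbind(do.call(rbind, pos_feat), neg_feat),
                labels = c(rep("exudate", n_pos),
                           rep("non_exudate", nrow(neg_feat))),
                manifest = bind_rows(
                  tibble(role = "positive", n = n_pos),
                  tibble(role = "negative", n = nrow(neg_feat))))
    attr(svm$features, "extractor_id") <- ex$id
  }
  list(svm = svm, det_patches = det_patches)
}

# 2:1 negative sampling, stratified half/half across the two pools when
# both suffice, excluding candidates above the black-fraction cap.
sample_svm_negatives <- function(neg_dr, neg_healthy, need, black_threshold,
                                 black_frac_max = 1 / 3, seed = NULL) {
  run <- function() {
    elig <- function(pool) {
      if (nrow(pool) == 0) return(pool)
      keep <- map_lgl(pool$pixels, function(px)
        black_fraction(px, black_threshold) <= black_frac_max)
      pool[keep, ]
    }
    dr <- elig(neg_dr); he <- elig(neg_healthy)
    if (nrow(dr) + nrow(he) < need) {
      abort(sprintf("insufficient eligible negative patches: need %d, have %d",
                    need, nrow(dr) + nrow(he)))
    }
    n_dr <- min(nrow(dr), max(need %/% 2L, need - nrow(he)))
    n_he <- need - n_dr
    bind_rows(if (n_dr > 0) dr[sample.int(nrow(dr), n_dr), ] else dr[0, ],
              if (n_he > 0) he[sample.int(nrow(he), n_he), ] else he[0, ])
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Run one cross-validated pipeline variant
#'
#' For each fold: trains the detector (and, when enabled, the SVM gate) on
#' the other folds, runs whole-image inference on the held-out images, and
#' accumulates exudate-level pixel tallies and image-level decisions. Fold
#' metrics are aggregated with [aggregate_folds()].
#'
#' @param manifest Dataset manifest (from [generate_dataset()]) with an
#'   added `image_id` column.
#' @param folds Fold assignment from [make_folds()].
#' @param config An [exuscan_config()]; its `use_gate` / `use_jitter`
#'   switches select the variant.
#' @return List of class `exu_cv_run`: `exudate_folds` and `image_folds`
#'   (per-fold metric tibbles), `exudate_summary` / `image_summary`
#'   (mean +/- sd), `image_scores` (per-image max patch score and label, for
#'   ROC), and bookkeeping counts.
#' @export
run_variant_cv <- function(manifest, folds, config) {
  ks <- sort(unique(folds$fold))
  ex_rows <- list(); im_rows <- list(); score_rows <- list()
  n_gated_out <- 0; n_patches <- 0
  for (k in ks) {
    tr <- gather_fold_training(manifest, folds, k, config)
    if (is.null(tr$det_patches)) {
      abort(sprintf("fold %d has no positive training patches", k))
    }
    det <- train_detector(tr$det_patches, config$detector,
                          config$black_threshold)
    gate <- NULL
    if (isTRUE(config$use_gate)) {
      if (is.null(tr$svm)) abort(sprintf("fold %d has no SVM training data", k))
      gate <- train_gate(tr$svm$features, tr$svm$labels, C = config$svm_C)
    }
    val_ids <- folds$image_id[folds$fold == k]
    counts <- c(tp = 0, fp = 0, fn = 0, tn = 0)
    decisions <- logical(); labels <- logical()
    for (id in val_ids) {
      row <- manifest[manifest$image_id == id, ]
      s <- load_sample(row)
      res <- detect_image(s$image, det, gate = gate,
                          extractor = config$extractor,
                          score_threshold = config$score_threshold,
                          source_id = id)
      ev <- evaluate_image(s$mask, res$detections,
                           overlap_min = config$overlap_min,
                           mode = config$match_mode)
      counts <- counts + unlist(ev$counts)
      dec <- image_level_decision(res$per_patch_scores$max_score, config$tau)
      decisions <- c(decisions, dec); labels <- c(labels, s$label)
      score_rows[[length(score_rows) + 1]] <-
        tibble(fold = k, image_id = id, label = s$label,
               score = if (nrow(res$per_patch_scores) > 0)
                 max(res$per_patch_scores$max_score) else 0)
      n_patches <- n_patches + nrow(res$per_patch_scores)
      n_gated_out <- n_gated_out + sum(!res$per_patch_scores$retained)
    }
    ex_rows[[k]] <- bind_cols(tibble(fold = k), compute_metrics(as.list(counts)),
                              tibble(tp = counts[["tp"]], fp = counts[["fp"]],
                                     fn = counts[["fn"]], tn = counts[["tn"]]))
    im_rows[[k]] <- bind_cols(tibble(fold = k),
                              image_level_metrics(decisions, labels))
  }
  ex_folds <- list_rbind(ex_rows); im_folds <- list_rbind(im_rows)
  metric_cols <- c("sensitivity", "specificity", "accuracy", "f1", "ppv",
                   "fpr", "fnr")
  structure(list(
    exudate_folds = ex_folds, image_folds = im_folds,
    exudate_summary = aggregate_folds(ex_folds[, metric_cols]),
    image_summary = aggregate_folds(im_folds[, metric_cols]),
    image_scores = list_rbind(score_rows),
    n_patches = n_patches, n_gated_out = n_gated_out,
    use_gate = isTRUE(config$use_gate), use_jitter = isTRUE(config$use_jitter)),
    class = "exu_cv_run")
}

#' @export
print.exu_cv_run <- function(x, ...) {
  cat(sprintf("<exu_cv_run> gate=%s jitter=%s, %d folds\n",
              x$use_gate, x$use_jitter, nrow(x$exudate_folds)))
  print(x$exudate_summary)
  invisible(x)
}

#' Run a named pipeline stage
#'
#' Stages mirror the end-to-end flow: `synth` writes the synthetic dataset,
#' `prepare` builds folds and the labelled base-grid patch manifest,
#' `build-svm-set` records the per-fold SVM set composition, `train-gate` /
#' `train-detector` fit and serialise the per-fold models, `detect` runs
#' gated inference on every held-out image, `evaluate` turns detections
#' into metrics at both levels, and `report` compares the four variants
#' (gate on/off x jitter on/off) in a mean +/- sd table with the relative
#' FPR/FNR changes attributable to the gate. Each stage is deterministic
#' given the config and seed, checks its prerequisites, and appends a
#' machine-readable entry to `run_log.json`.
#'
#' @param name One of `"synth"`, `"prepare"`, `"build-svm-set"`,
#'   `"train-gate"`, `"train-detector"`, `"detect"`, `"evaluate"`,
#'   `"report"`.
#' @param config An [exuscan_config()].
#' @return The stage's main artifact (tibble or list), invisibly where it
#'   is primarily written to disk.
#' @export
run_command <- function(name, config) {
  stopifnot(inherits(config, "exuscan_config"))
  stages <- c("synth", "prepare", "build-svm-set", "train-gate",
              "train-detector", "detect", "evaluate", "report")
  if (!name %in% stages) {
    abort(sprintf("unknown stage '%s' (expected one of: %s)", name,
                  paste(stages, collapse = ", ")))
  }
  p <- pipe_paths(config)
  if (!dir.exists(p$dir)) dir.create(p$dir, recursive = TRUE)
  switch(name,
    "synth" = st_synth(config, p),
    "prepare" = st_prepare(config, p),
    "build-svm-set" = st_build_svm(config, p),
    "train-gate" = st_train_gate(config, p),
    "train-detector" = st_train_detector(config, p),
    "detect" = st_detect(config, p),
    "evaluate" = st_evaluate(config, p),
    "report" = st_report(config, p))
}

st_synth <- function(config, p) {
  synth <- config$synth
  synth$seed <- derive_seed(config$seed, "synth")
  manifest <- generate_dataset(synth, config$n_images,
                               config$positive_fraction, p$data)
  append_log(config, "synth", list(n_images = nrow(manifest),
                                   n_positive = sum(manifest$label == "exudates")))
  invisible(manifest)
}

read_manifest <- function(p, stage) {
  require_artifact(p$manifest, stage)
  m <- as_tibble(read.csv(p$manifest, stringsAsFactors = FALSE))
  m$image_id <- sub("\\.png$", "", basename(m$image_path))
  m
}

st_prepare <- function(config, p) {
  manifest <- read_manifest(p, "prepare")
  folds <- make_folds(manifest$image_id[manifest$label == "exudates"],
                      manifest$image_id[manifest$label == "healthy"],
                      k = config$k_folds,
                      seed = derive_seed(config$seed, "folds"))
  write.csv(folds, p$folds, row.names = FALSE)
  patch_rows <- list()
  for (i in seq_len(nrow(manifest))) {
    s <- load_sample(manifest[i, ])
    padded <- pad_to_multiple(s$image, config$tile)
    objects <- mask_to_objects(s$mask)
    grid <- label_patches(tile_patches(padded, manifest$image_id[i]), objects,
                          config$tile)
    patch_rows[[i]] <- grid[, c("source_id", "origin_x", "origin_y",
                                "provenance", "label")]
  }
  patches <- list_rbind(patch_rows)
  write.csv(patches, p$patches, row.names = FALSE)
  append_log(config, "prepare", list(n_patches = nrow(patches),
                                     n_exudate_patches = sum(patches$label == "exudate")))
  invisible(list(folds = folds, patches = patches))
}

read_folds <- function(p, stage) {
  require_artifact(p$folds, stage)
  as_tibble(read.csv(p$folds, stringsAsFactors = FALSE))
}

st_build_svm <- function(config, p) {
  manifest <- read_manifest(p, "build-svm-set")
  folds <- read_folds(p, "build-svm-set")
  rows <- list()
  for (k in sort(unique(folds$fold))) {
    tr <- gather_fold_training(manifest, folds, k, config)
    if (is.null(tr$svm)) abort(sprintf("fold %d has no SVM training data", k))
    rows[[k]] <- bind_cols(tibble(fold = k), tr$svm$manifest)
  }
  sets <- list_rbind(rows)
  write.csv(sets, p$svm_sets, row.names = FALSE)
  append_log(config, "build-svm-set", list(n_rows = nrow(sets)))
  invisible(sets)
}

st_train_gate <- function(config, p) {
  manifest <- read_manifest(p, "train-gate")
  folds <- read_folds(p, "train-gate")
  gates <- list()
  for (k in sort(unique(folds$fold))) {
    tr <- gather_fold_training(manifest, folds, k, config)
    if (is.null(tr$svm)) abort(sprintf("fold %d has no SVM training data", k))
    g <- train_gate(tr$svm$features, tr$svm$labels, C = config$svm_C)
    gates[[as.character(k)]] <- list(weights = g$weights, bias = g$bias,
                                     C = g$C, extractor_id = g$extractor_id)
  }
  jsonlite::write_json(gates, p$gates, auto_unbox = TRUE, digits = NA)
  append_log(config, "train-gate", list(n_folds = length(gates)))
  invisible(gates)
}

st_train_detector <- function(config, p) {
  manifest <- read_manifest(p, "train-detector")
  folds <- read_folds(p, "train-detector")
  models <- list()
  for (k in sort(unique(folds$fold))) {
    tr <- gather_fold_training(manifest, folds, k, config)
    if (is.null(tr$det_patches)) abort(sprintf("fold %d has no detector training patches", k))
    m <- train_detector(tr$det_patches, config$detector, config$black_threshold)
    models[[as.character(k)]] <- list(backend = m$backend, params = m$params,
                                      anchors = m$anchors,
                                      learning_rate = m$config$learning_rate,
                                      mini_batch = m$config$mini_batch,
                                      epochs = m$config$epochs)
  }
  jsonlite::write_json(models, p$detectors, auto_unbox = TRUE, digits = NA)
  append_log(config, "train-detector", list(n_folds = length(models)))
  invisible(models)
}

load_fold_models <- function(config, p, stage) {
  require_artifact(p$detectors, stage)
  require_artifact(p$gates, stage)
  dets <- jsonlite::read_json(p$detectors)
  gates <- jsonlite::read_json(p$gates)
  list(
    detector = function(k) {
      m <- dets[[as.character(k)]]
      structure(list(backend = m$backend,
                     params = map(m$params, as.numeric),
                     anchors = as_tibble(do.call(rbind, map(m$anchors, as.data.frame))),
                     config = config$detector, trained = TRUE),
                class = "exu_detector")
    },
    gate = function(k) {
      g <- gates[[as.character(k)]]
      structure(list(weights = as.numeric(unlist(g$weights)),
                     bias = as.numeric(g$bias), C = as.numeric(g$C),
                     extractor_id = g$extractor_id, n_support = NA_integer_),
                class = "exu_gate")
    })
}

st_detect <- function(config, p) {
  manifest <- read_manifest(p, "detect")
  folds <- read_folds(p, "detect")
  models <- load_fold_models(config, p, "detect")
  det_rows <- list(); score_rows <- list()
  for (k in sort(unique(folds$fold))) {
    det <- models$detector(k)
    gate <- if (isTRUE(config$use_gate)) models$gate(k)
    for (id in folds$image_id[folds$fold == k]) {
      s <- load_sample(manifest[manifest$image_id == id, ])
      res <- detect_image(s$image, det, gate = gate,
                          extractor = config$extractor,
                          score_threshold = config$score_threshold,
                          source_id = id)
      if (nrow(res$detections) > 0) {
        det_rows[[length(det_rows) + 1]] <-
          bind_cols(tibble(image_id = id, fold = k), res$detections)
      }
      score_rows[[length(score_rows) + 1]] <-
        bind_cols(tibble(fold = k), res$per_patch_scores)
    }
  }
  detections <- if (length(det_rows)) list_rbind(det_rows) else
    tibble(image_id = character(), fold = integer(), x0 = numeric(),
           y0 = numeric(), x1 = numeric(), y1 = numeric(), score = numeric())
  scores <- list_rbind(score_rows)
  write.csv(detections, p$detections, row.names = FALSE)
  write.csv(scores, p$patch_scores, row.names = FALSE)
  append_log(config, "detect",
             list(n_detections = nrow(detections),
                  n_patches = nrow(scores),
                  n_gated_out = sum(!scores$retained)))
  invisible(list(detections = detections, patch_scores = scores))
}

st_evaluate <- function(config, p) {
  manifest <- read_manifest(p, "evaluate")
  folds <- read_folds(p, "evaluate")
  require_artifact(p$detections, "evaluate")
  require_artifact(p$patch_scores, "evaluate")
  detections <- as_tibble(read.csv(p$detections, stringsAsFactors = FALSE))
  scores <- as_tibble(read.csv(p$patch_scores, stringsAsFactors = FALSE))
  ex_rows <- list(); im_rows <- list()
  for (k in sort(unique(folds$fold))) {
    counts <- c(tp = 0, fp = 0, fn = 0, tn = 0)
    decisions <- logical(); labels <- logical()
    for (id in folds$image_id[folds$fold == k]) {
      s <- load_sample(manifest[manifest$image_id == id, ])
      d <- detections[detections$image_id == id,
                      c("x0", "y0", "x1", "y1", "score")]
      ev <- evaluate_image(s$mask, d, overlap_min = config$overlap_min,
                           mode = config$match_mode)
      counts <- counts + unlist(ev$counts)
      sc <- scores$max_score[scores$source_id == id]
      decisions <- c(decisions, image_level_decision(sc, config$tau))
      labels <- c(labels, s$label)
    }
    ex_rows[[k]] <- bind_cols(tibble(fold = k), compute_metrics(as.list(counts)))
    im_rows[[k]] <- bind_cols(tibble(fold = k),
                              image_level_metrics(decisions, labels))
  }
  metric_cols <- c("sensitivity", "specificity", "accuracy", "f1", "ppv",
                   "fpr", "fnr")
  ex_folds <- list_rbind(ex_rows); im_folds <- list_rbind(im_rows)
  out <- list(
    exudate_level = list(per_fold = ex_folds,
                         summary = aggregate_folds(ex_folds[, metric_cols])),
    image_level = list(per_fold = im_folds,
                       summary = aggregate_folds(im_folds[, metric_cols])))
  jsonlite::write_json(out, p$evaluation, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  append_log(config, "evaluate", list(written = p$evaluation))
  invisible(out)
}

st_report <- function(config, p) {
  manifest <- read_manifest(p, "report")
  folds <- read_folds(p, "report")
  variants <- tibble(variant = c("rcnn", "rcnn_svm", "rcnn_ca", "rcnn_ca_svm"),
                     use_gate = c(FALSE, TRUE, FALSE, TRUE),
                     use_jitter = c(FALSE, FALSE, TRUE, TRUE))
  rows <- list()
  for (i in seq_len(nrow(variants))) {
    cfg_v <- config
    cfg_v$use_gate <- variants$use_gate[i]
    cfg_v$use_jitter <- variants$use_jitter[i]
    run <- run_variant_cv(manifest, folds, cfg_v)
    rows[[length(rows) + 1]] <- bind_rows(
      mutate(run$exudate_summary, level = "exudate"),
      mutate(run$image_summary, level = "image")) |>
      mutate(variant = variants$variant[i])
  }
  report <- list_rbind(rows)[, c("variant", "level", "metric", "mean", "sd")]
  write.csv(report, p$report_csv, row.names = FALSE)
  deltas <- svm_contribution_report(report)
  write.csv(deltas, p$report_deltas, row.names = FALSE)
  append_log(config, "report", list(n_rows = nrow(report)))
  invisible(list(summary = report, deltas = deltas))
}

#' Run the full pipeline end to end
#'
#' Chains `synth`, `prepare`, `build-svm-set`, `train-gate`,
#' `train-detector`, `detect` and `evaluate` for the configured variant.
#'
#' @param config An [exuscan_config()].
#' @return The evaluation result (see the `evaluate` stage), invisibly.
#' @export
run_pipeline <- function(config) {
  for (stage in c("synth", "prepare", "build-svm-set", "train-gate",
                  "train-detector", "detect", "evaluate")) {
    out <- run_command(stage, config)
  }
  invisible(out)
}
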