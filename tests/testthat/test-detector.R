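test_that("anchor dimensions are box-size quantiles", {
  b <- boxes_tbl(x0 = c(0, 0, 0), y0 = c(0, 0, 0),
                 x1 = c(8, 16, 32), y1 = c(8, 16, 32))
  a <- derive_anchors(b, n_anchors = 3)
  expect_equal(a$w, c(8, 16, 32))
  expect_equal(a$h, c(8, 16, 32))
  # degenerate distribution: every anchor identical
  deg <- boxes_tbl(x0 = rep(0, 4), y0 = rep(0, 4),
                   x1 = rep(16, 4), y1 = rep(16, 4))
  a2 <- derive_anchors(deg, n_anchors = 5)
  expect_true(all(a2$w == 16) && all(a2$h == 16))
  # permutation invariance
  perm <- b[c(3, 1, 2), ]
  expect_equal(derive_anchors(perm, 3), a)
  expect_error(derive_anchors(b[0, ], 3), "empty")
})

test_that("anchors are labelled by IoU intervals with a disjoint split", {
  gt <- boxes_tbl(0, 0, 10, 10)
  # IoUs: 1, exactly 0.1 (10/100), 0
  anchors <- boxes_tbl(x0 = c(0, 0, 50), y0 = c(0, 0, 50),
                       x1 = c(10, 10, 60), y1 = c(10, 1, 60))
  lab <- label_anchors(anchors, gt)
  expect_equal(lab$max_iou, c(1, 0.1, 0))
  # the boundary 0.1 belongs to the positive interval, not the negative one
  expect_equal(lab$label, c("positive", "positive", "negative"))
  lab2 <- label_anchors(anchors, gt, positive_overlap = c(0.5, 1))
  expect_equal(lab2$label, c("positive", "ignored", "negative"))
})

test_that("the detector config validates and echoes its training settings", {
  cfg <- detector_config()
  expect_equal(cfg$learning_rate, 3e-4)
  expect_equal(cfg$mini_batch, 2L)
  expect_equal(cfg$epochs, 10L)
  expect_equal(cfg$negative_overlap, c(0, 0.1))
  expect_equal(cfg$positive_overlap, c(0.1, 1))
  expect_error(detector_config(epochs = 0), "epochs")
  expect_error(detector_config(negative_overlap = c(0, 0.5),
                               positive_overlap = c(0.2, 1)), "overlap")
  # the trained model's glance echoes the configuration
  px <- blob_patch(blobs = list(list(x = 80, y = 80, r = 12, gain = 80)),
                   noise = 3)
  tp <- patch_row(px)
  tp$boxes <- list(boxes_tbl(66, 66, 94, 94))
  m <- train_detector(tp, cfg)
  g <- glance(m)
  expect_equal(g$learning_rate, 3e-4)
  expect_equal(g$mini_batch, 2L)
  expect_equal(g$epochs, 10L)
})

test_that("training rejects patches without ground-truth boxes", {
  tp <- patch_row(blob_patch())
  tp$boxes <- list(boxes_tbl())
  expect_error(train_detector(tp), "without ground-truth boxes")
})

test_that("reference training fits deterministic percentile parameters", {
  px <- blob_patch(blobs = list(list(x = 80, y = 80, r = 12, gain = 80)),
                   noise = 3, seed = 5)
  tp <- patch_row(px)
  tp$boxes <- list(boxes_tbl(66, 66, 94, 94))
  m1 <- train_detector(tp)
  m2 <- train_detector(tp)
  expect_identical(m1$params, m2$params)
  expect_true(m1$params$delta < 80 && m1$params$delta > 0)
  expect_true(m1$params$saturation >= m1$params$delta)
})

test_that("the reference detector finds separated blobs and nothing on flat input", {
  params <- list(delta = 25, saturation = 60, min_area = 4,
                 black_threshold = 10)
  expect_equal(nrow(reference_detect(blob_patch(base = 100), params)), 0)
  two <- blob_patch(base = 100,
                    blobs = list(list(x = 50, y = 50, r = 10, gain = 70),
                                 list(x = 160, y = 160, r = 12, gain = 80)))
  d <- reference_detect(two, params)
  expect_equal(nrow(d), 2)
  expect_true(all(d$score >= 0 & d$score <= 1))
  expect_true(all(diff(d$score) <= 0))  # sorted descending
  # detection count is monotone non-increasing in the threshold
  counts <- vapply(seq(10, 90, by = 10), function(delta) {
    p <- params; p$delta <- delta
    nrow(reference_detect(two, p))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("the early-stopping monitor fires after consecutive worsenings", {
  m <- early_stopping(patience = 5)
  errs <- c(1.0, 0.9, 0.95, 0.97, 1.0, 1.1)  # 4 consecutive worsenings
  expect_false(any(vapply(errs, m, logical(1))))
  expect_true(m(1.2))  # fifth in a row
  # a single improvement resets the count
  m2 <- early_stopping(patience = 2)
  expect_false(m2(1)); expect_false(m2(2)); expect_false(m2(0.5))
  expect_false(m2(0.6)); expect_true(m2(0.7))
})

test_that("patch detection respects thresholds and patch bounds", {
  px <- blob_patch(base = 100, noise = 3,
                   blobs = list(list(x = 60, y = 70, r = 10, gain = 85)))
  tp <- patch_row(px)
  tp$boxes <- list(boxes_tbl(50, 60, 70, 80))
  m <- train_detector(tp)
  d <- detect(m, tp, score_threshold = 0.3)
  expect_gte(nrow(d), 1)
  expect_true(all(d$x0 >= 0 & d$y0 >= 0 & d$x1 <= 224 & d$y1 <= 224))
  # the top detection intersects the true lesion box
  inter <- exuscan:::box_intersection_area(d[1, ], tp$boxes[[1]])
  expect_gt(inter, 0)
  # blank patch: nothing
  expect_equal(nrow(detect(m, patch_row(blob_patch(base = 100)), 0.3)), 0)
  # threshold 1 keeps only saturated scores; out-of-range threshold rejected
  d1 <- detect(m, tp, score_threshold = 1)
  expect_true(all(d1$score == 1))
  expect_error(detect(m, tp, score_threshold = 1.01), "0, 1")
  untrained <- m; untrained$trained <- FALSE
  expect_error(detect(untrained, tp), "not trained")
})

test_that("whole-image inference composes tiling, gating and coordinates", {
  s <- generate_fundus(synth_config(width = 600, height = 400,
                                    n_lesions = c(2, 3),
                                    lesion_radius = c(5, 12),
                                    lesion_gain = c(70, 90),
                                    cluster_frac = 1, seed = 14))
  padded <- pad_to_multiple(s$image)
  objs <- mask_to_objects(s$mask)
  grid <- label_patches(tile_patches(padded), objs)
  tp <- grid[grid$label == "exudate", ]
  model <- train_detector(tp)
  res <- detect_image(s$image, model, score_threshold = 0.3)
  # detections lie within the original image bounds (never in the padding)
  expect_true(all(res$detections$x1 <= 600))
  expect_true(all(res$detections$y1 <= 400))
  expect_equal(nrow(res$per_patch_scores), 6)
  # at least one detection overlaps the true mask
  filled <- fill_boxes(res$detections, dim(s$mask))
  expect_gt(sum(filled & s$mask > 0), 0)
  # oracle gate rejecting everything: no detections, all scores zero
  res0 <- detect_image(s$image, model,
                       gate = function(p) rep(FALSE, nrow(p)),
                       score_threshold = 0.3)
  expect_equal(nrow(res0$detections), 0)
  expect_true(all(res0$per_patch_scores$max_score == 0))
  expect_true(all(!res0$per_patch_scores$retained))
  # a trained gate can only remove detections relative to the ungated run
  ex <- toy_extractor()
  neg <- grid[grid$label == "non_exudate", ]
  feats <- extract_features(dplyr::bind_rows(tp, neg), ex)
  gate <- train_gate(feats, c(rep("exudate", nrow(tp)),
                              rep("non_exudate", nrow(neg))))
  resg <- detect_image(s$image, model, gate = gate, extractor = ex,
                       score_threshold = 0.3)
  key <- function(d) paste(d$x0, d$y0, d$x1, d$y1, round(d$score, 10))
  expect_true(all(key(resg$detections) %in% key(res$detections)))
  expect_error(detect_image(s$image, model, gate = gate), "extractor")
})
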