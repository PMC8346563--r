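test_that("box filling rasterises unions correctly", {
  one <- fill_boxes(boxes_tbl(2, 3, 12, 13), c(20, 20))
  expect_equal(sum(one), 100)
  # union of overlapping boxes, against inclusion-exclusion
  two <- fill_boxes(boxes_tbl(c(0, 5), c(0, 5), c(10, 15), c(10, 15)),
                    c(20, 20))
  expect_equal(sum(two), 100 + 100 - 25)
  expect_equal(sum(fill_boxes(boxes_tbl(), c(20, 20))), 0)
  expect_error(fill_boxes(boxes_tbl(0, 0, 30, 5), c(20, 20)), "outside")
})

test_that("the 20% rule is strict and any-overlap mode accepts single pixels", {
  shape <- c(40, 40)
  gt <- tibble::tibble(component_id = 1L, x0 = 0, y0 = 0, x1 = 10, y1 = 10,
                       pixel_count = 100L)
  # 25 of 100 pixels covered: found
  d25 <- boxes_tbl(5, 5, 15, 15)
  m <- match_exudate_level(gt, d25, shape)
  expect_true(m$gt_status$found)
  expect_equal(m$counts$tp, 100)
  expect_equal(m$counts$fn, 0)
  # exactly 20 of 100: NOT found (strictly more than 20% required)
  d20 <- boxes_tbl(0, 8, 10, 12)
  m20 <- match_exudate_level(gt, d20, shape)
  expect_false(m20$gt_status$found)
  expect_equal(m20$counts$fn, 100)
  # the same detection counts as found under any-overlap
  m_any <- match_exudate_level(gt, d20, shape, mode = "any_overlap")
  expect_true(m_any$gt_status$found)
  # single-pixel intersection suffices in any-overlap mode
  d1 <- boxes_tbl(9, 9, 19, 19)
  expect_true(match_exudate_level(gt, d1, shape,
                                  mode = "any_overlap")$gt_status$found)
  expect_false(match_exudate_level(gt, d1, shape)$gt_status$found)
  # no detections: all ground-truth pixels are misses
  m0 <- match_exudate_level(gt, boxes_tbl(), shape)
  expect_equal(unlist(m0$counts), c(tp = 0, fp = 0, fn = 100, tn = 1500))
  expect_error(match_exudate_level(gt, d25, shape, overlap_min = 1),
               "overlap_min")
})

test_that("matching agrees with the pixel-set oracle on random scenes", {
  set.seed(42)
  for (rep in 1:60) {
    h <- sample(24:64, 1); w <- sample(24:64, 1)
    gt_b <- random_boxes(sample(0:5, 1), h, w)
    det_b <- random_boxes(sample(0:6, 1), h, w)
    gt <- tibble::as_tibble(cbind(component_id = seq_len(nrow(gt_b)), gt_b))
    mode <- sample(c("strict", "any_overlap"), 1)
    got <- match_exudate_level(gt, tibble::as_tibble(det_b), c(h, w),
                               mode = mode)
    want <- oracle_match(gt_b, det_b, c(h, w), mode = mode)
    expect_equal(unlist(got$counts),
                 c(tp = want$tp, fp = want$fp, fn = want$fn, tn = want$tn))
    expect_equal(got$gt_status$found, want$found)
    expect_equal(got$det_status$matched, want$matched)
    # conservation
    expect_equal(sum(unlist(got$counts)), h * w)
  }
})

test_that("lowering the overlap threshold never loses found objects", {
  set.seed(9)
  for (rep in 1:10) {
    h <- 48; w <- 48
    gt_b <- random_boxes(4, h, w)
    det_b <- random_boxes(5, h, w)
    gt <- tibble::as_tibble(cbind(component_id = 1:4, gt_b))
    found <- vapply(c(0.5, 0.3, 0.2, 0.1, 0), function(om) {
      sum(match_exudate_level(gt, tibble::as_tibble(det_b), c(h, w),
                              overlap_min = om)$gt_status$found)
    }, numeric(1))
    expect_true(all(diff(found) >= 0))
  }
})

test_that("metric formulas and their identities hold", {
  m <- compute_metrics(list(tp = 9, fn = 1, fp = 0, tn = 90))
  expect_equal(m$sensitivity, 0.9)
  expect_equal(m$fnr, 0.1)
  expect_equal(m$ppv, 1)
  expect_equal(m$f1, 2 * 0.9 * 1 / 1.9)
  expect_equal(compute_metrics(list(tp = 5, fn = 0, fp = 0, tn = 5))$f1, 1)
  # undefined denominators surface as NA
  und <- compute_metrics(list(tp = 0, fn = 0, fp = 3, tn = 7))
  expect_true(is.na(und$sensitivity) && is.na(und$fnr))
  all0 <- compute_metrics(list(tp = 0, fn = 0, fp = 0, tn = 0))
  expect_true(all(is.na(unlist(all0))))
  # random counts vs long-hand fractions, plus the rate identities
  set.seed(14)
  for (rep in 1:20) {
    cts <- as.list(setNames(sample(1:50, 4, replace = TRUE),
                            c("tp", "fp", "fn", "tn")))
    g <- compute_metrics(cts)
    expect_equal(g$sensitivity, cts$tp / (cts$tp + cts$fn))
    expect_equal(g$specificity, cts$tn / (cts$tn + cts$fp))
    expect_equal(g$ppv, cts$tp / (cts$tp + cts$fp))
    expect_equal(g$accuracy,
                 (cts$tp + cts$tn) / Reduce(`+`, cts))
    expect_equal(g$sensitivity + g$fnr, 1)
    expect_equal(g$specificity + g$fpr, 1)
  }
})

test_that("the image-level rule thresholds the maximum patch score", {
  expect_true(image_level_decision(c(0.3, 0.95)))
  expect_false(image_level_decision(c(0.89)))
  expect_true(image_level_decision(c(0.9)))  # equal-to counts as positive
  expect_false(image_level_decision(numeric()))
  expect_error(image_level_decision(c(0.5, 1.2)), "0, 1")
  # image-count metrics
  all_ok <- image_level_metrics(c(TRUE, FALSE, TRUE), c(TRUE, FALSE, TRUE))
  expect_equal(all_ok$accuracy, 1)
  fp_all <- image_level_metrics(rep(TRUE, 4), rep(FALSE, 4))
  expect_equal(fp_all$fpr, 1)
  expect_equal(fp_all$specificity, 0)
  hand <- image_level_metrics(c(TRUE, TRUE, FALSE, FALSE, TRUE),
                              c(TRUE, FALSE, TRUE, FALSE, TRUE))
  expect_equal(unlist(hand[, c("sensitivity", "specificity")]),
               c(sensitivity = 2 / 3, specificity = 1 / 2))
})

test_that("AUC equals the rank probability and matches an external check", {
  expect_equal(roc_auc(c(0.1, 0.2, 0.8, 0.9), c(FALSE, FALSE, TRUE, TRUE)), 1)
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(FALSE, FALSE, TRUE, TRUE)), 0)
  expect_equal(roc_auc(c(0.5, 0.5), c(TRUE, FALSE)), 0.5)  # tie counts half
  set.seed(8)
  sc <- runif(2000); lb <- runif(2000) < 0.5
  expect_lt(abs(roc_auc(sc, lb) - 0.5), 0.05)
  expect_error(roc_auc(c(0.1, 0.2), c(TRUE, TRUE)), "both classes")
  skip_if_not_installed("pROC")
  set.seed(15)
  sc2 <- c(rnorm(40, 1), rnorm(60))
  lb2 <- rep(c(TRUE, FALSE), c(40, 60))
  ext <- as.numeric(pROC::auc(pROC::roc(lb2, sc2, quiet = TRUE,
                                        direction = "<")))
  expect_equal(roc_auc(sc2, lb2), ext, tolerance = 1e-10)
})

test_that("relative change recovers the printed gate contributions", {
  expect_equal(relative_change(0.0037, 0.0026), -29.72973, tolerance = 1e-5)
  expect_equal(relative_change(0.5143, 0.2571), -50.00972, tolerance = 1e-5)
  expect_equal(relative_change(0.4, 0.4), 0)
  expect_error(relative_change(0, 0.1), "positive")
})

test_that("fold aggregation averages each metric, F1 included, per fold", {
  f <- tibble::tibble(sensitivity = c(0.8, 1.0), ppv = c(0.5, 0.9),
                      f1 = c(2 * .8 * .5 / 1.3, 2 * 1 * .9 / 1.9))
  agg <- aggregate_folds(f)
  expect_equal(agg$mean[agg$metric == "sensitivity"], 0.9)
  expect_equal(agg$mean[agg$metric == "f1"], mean(f$f1))
  # mean F1 is NOT F1 of the means -- per-fold averaging is observable
  f1_of_means <- 2 * 0.9 * 0.7 / 1.6
  expect_false(isTRUE(all.equal(agg$mean[agg$metric == "f1"], f1_of_means)))
  # identical folds: zero spread
  same <- tibble::tibble(sensitivity = c(0.7, 0.7, 0.7))
  expect_equal(aggregate_folds(same)$sd, 0)
  # long-hand oracle on random metric tables
  set.seed(30)
  r <- tibble::tibble(a = runif(5), b = runif(5))
  agg2 <- aggregate_folds(r)
  expect_equal(agg2$mean, c(mean(r$a), mean(r$b)))
  expect_equal(agg2$sd, c(sd(r$a), sd(r$b)))
  expect_error(aggregate_folds(r[0, ]), "no folds")
})

test_that("the published summary reproduces the headline gate deltas", {
  rep <- svm_contribution_report()
  get <- function(level, ca, metric) {
    rep$change_pct[rep$level == level & rep$contrast_adjusted == ca &
                     rep$metric == metric]
  }
  expect_equal(get("exudate", TRUE, "fpr"), -29.73, tolerance = 0.01)
  expect_equal(get("exudate", FALSE, "fpr"), -23.40, tolerance = 0.01)
  expect_equal(get("exudate", TRUE, "fnr"), 16.21, tolerance = 0.01)
  expect_equal(get("exudate", FALSE, "fnr"), 17.97, tolerance = 0.01)
  expect_equal(get("image", TRUE, "fpr"), -50.0, tolerance = 0.02)
  expect_equal(get("image", FALSE, "fpr"), -23.07, tolerance = 0.01)
  # image-level FNR pairs have zero baseline or zero change
  expect_true(all(is.na(get("image", TRUE, "fnr")) |
                    get("image", TRUE, "fnr") == 0))
})
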