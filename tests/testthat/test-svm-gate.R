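test_that("the toy extractor has a closed form on an all-zero patch", {
  ex <- toy_extractor(bins = 8)
  z <- array(0, dim = c(224, 224, 3))
  f <- extract_features(patch_row(z), ex)
  expect_equal(ncol(f), ex$dim)
  # all histogram mass in the first bin of each channel
  expect_equal(as.numeric(f[1, c(1, 9, 17)]), rep(1, 3))
  expect_equal(as.numeric(f[1, c(2:8, 10:16, 18:24)]), rep(0, 21))
  # zero gradients and zero brightness statistics
  expect_equal(as.numeric(f[1, 25:36]), rep(0, 12))
  # determinism
  px <- blob_patch(blobs = list(list(x = 30, y = 40, r = 8, gain = 70)),
                   noise = 3)
  expect_identical(extract_features(patch_row(px), ex),
                   extract_features(patch_row(px), ex))
  expect_error(extract_features(patch_row(array(0, dim = c(64, 64, 3))), ex),
               "224")
})

test_that("the pooled embedding extractor honours its length contract", {
  ex <- pooled_embedding_extractor(dim = 64, seed = 3)
  px <- blob_patch(noise = 2)
  f <- extract_features(patch_row(px), ex)
  expect_equal(ncol(f), 64)
  expect_true(all(is.finite(f)))
  # deterministic given (dim, seed), including across fresh constructions
  ex2 <- pooled_embedding_extractor(dim = 64, seed = 3)
  expect_identical(f, extract_features(patch_row(px), ex2))
  expect_false(identical(f, extract_features(
    patch_row(px), pooled_embedding_extractor(dim = 64, seed = 4))))
})

test_that("gate training finds the symmetric separator and classifies it", {
  X <- matrix(c(-1, 1), ncol = 1)
  m <- train_gate(X, c("non_exudate", "exudate"))
  cls <- gate_classify(m, X)
  expect_equal(cls$label, c("non_exudate", "exudate"))
  # the midpoint margin is ~0 and ties go to the positive class
  expect_equal(as.numeric(m$weights %*% 0 + m$bias), 0, tolerance = 1e-6)
  expect_equal(gate_classify(m, matrix(0))$label, "exudate")
  # separable set trains to perfect accuracy
  set.seed(1)
  X2 <- rbind(matrix(rnorm(40, -3), 20, 2), matrix(rnorm(40, 3), 20, 2))
  y2 <- rep(c("non_exudate", "exudate"), each = 20)
  m2 <- train_gate(X2, y2)
  expect_equal(gate_classify(m2, X2)$label, y2)
  expect_error(train_gate(X2, rep("exudate", 40)), "both classes")
  expect_error(gate_classify(m2, matrix(0, 1, 5)), "length")
})

test_that("decision values match a brute-force hinge-loss optimiser", {
  set.seed(7)
  for (rep in 1:4) {
    n <- sample(4:6, 1)
    X <- matrix(rnorm(2 * n, sd = 2), n, 2)
    y <- c(-1, 1, sample(c(-1, 1), n - 2, replace = TRUE))
    m <- train_gate(X, ifelse(y > 0, "exudate", "non_exudate"))
    oracle <- oracle_linear_svm(X, y, C = 1)
    got <- drop(X %*% m$weights) + m$bias
    want <- drop(X %*% oracle$w) + oracle$b
    expect_equal(got, want, tolerance = 0.05)
    # implementation achieves (at least) the oracle objective value
    hinge <- function(w, b) 0.5 * sum(w^2) + sum(pmax(0, 1 - y * (X %*% w + b)))
    expect_lte(hinge(m$weights, m$bias), oracle$value + 1e-3)
  }
})

test_that("classification is antisymmetric and matches the dot product", {
  set.seed(2)
  m <- structure(list(weights = rnorm(3), bias = 0.3, C = 1,
                      extractor_id = "x", n_support = 0L),
                 class = "exu_gate")
  X <- matrix(rnorm(30), 10, 3)
  cls <- gate_classify(m, X)
  expect_equal(cls$margin, drop(X %*% m$weights) + m$bias)
  expect_equal(cls$label, ifelse(cls$margin >= 0, "exudate", "non_exudate"))
  m_neg <- m; m_neg$weights <- -m$weights; m_neg$bias <- -m$bias
  cls2 <- gate_classify(m_neg, X)
  flip <- cls$margin != 0
  expect_equal(cls2$label[flip],
               ifelse(cls$label[flip] == "exudate", "non_exudate", "exudate"))
})

test_that("gate filtering preserves order, recomputes labels, and is idempotent", {
  ex <- toy_extractor()
  pos_px <- blob_patch(blobs = list(list(x = 100, y = 100, r = 15, gain = 90)))
  neg_px <- blob_patch()
  patches <- dplyr::bind_rows(
    patch_row(neg_px, id = "a"), patch_row(pos_px, id = "b"),
    patch_row(neg_px, id = "c"), patch_row(pos_px, id = "d"))
  feats <- extract_features(patches, ex)
  model <- train_gate(feats, c("non_exudate", "exudate", "non_exudate",
                               "exudate"))
  kept <- gate_filter(patches, model, ex)
  manual <- gate_classify(model, feats)
  expect_equal(kept$source_id, patches$source_id[manual$label == "exudate"])
  # idempotence
  again <- gate_filter(kept, model, ex)
  expect_equal(again$source_id, kept$source_id)
  # accept-everything / reject-everything models
  acc <- structure(list(weights = rep(0, ex$dim), bias = 1, C = 1,
                        extractor_id = ex$id, n_support = 0L),
                   class = "exu_gate")
  rej <- structure(list(weights = rep(0, ex$dim), bias = -1, C = 1,
                        extractor_id = ex$id, n_support = 0L),
                   class = "exu_gate")
  expect_equal(gate_filter(patches, acc, ex)$source_id, patches$source_id)
  expect_equal(nrow(gate_filter(patches, rej, ex)), 0)
})

test_that("positive feature scaling preserves separability", {
  set.seed(5)
  X <- rbind(matrix(rnorm(20, -2), 10, 2), matrix(rnorm(20, 2), 10, 2))
  y <- rep(c("non_exudate", "exudate"), each = 10)
  for (s in c(0.01, 1, 50)) {
    m <- train_gate(X * s, y, C = 100)
    expect_equal(gate_classify(m, X * s)$label, y)
  }
})

test_that("cross-validated accuracy behaves at the extremes", {
  set.seed(3)
  # identical, separable data in every fold -> mean accuracy 1
  Xf <- rbind(matrix(rnorm(20, -3), 10, 2), matrix(rnorm(20, 3), 10, 2))
  X <- rbind(Xf, Xf, Xf)
  y <- rep(rep(c("non_exudate", "exudate"), each = 10), 3)
  folds <- rep(1:3, each = 20)
  cv <- gate_cv_accuracy(X, y, folds)
  expect_equal(cv$mean_accuracy, 1)
  expect_equal(nrow(cv$per_fold), 3)
  # labels independent of features: accuracy near the majority rate
  set.seed(11)
  n <- 600
  Xr <- matrix(rnorm(2 * n), n, 2)
  yr <- ifelse(runif(n) < 0.7, "non_exudate", "exudate")
  cvr <- gate_cv_accuracy(Xr, yr, rep(1:3, length.out = n))
  expect_lt(abs(cvr$mean_accuracy - max(table(yr)) / n), 0.08)
})

test_that("the gate beats the majority baseline on high-contrast lesions", {
  # synthetic lesion patches with gain far above noise vs background patches
  set.seed(21)
  mk <- function(i, lesion) {
    blobs <- if (lesion) list(list(x = runif(1, 40, 180), y = runif(1, 40, 180),
                                   r = runif(1, 6, 15), gain = 85)) else list()
    patch_row(blob_patch(base = 110, blobs = blobs, noise = 4, seed = 100 + i),
              id = paste0("s", i))
  }
  patches <- dplyr::bind_rows(lapply(1:36, function(i) mk(i, i <= 12)))
  labels <- c(rep("exudate", 12), rep("non_exudate", 24))
  feats <- extract_features(patches, toy_extractor())
  cv <- gate_cv_accuracy(feats, labels, rep(1:3, length.out = 36))
  majority <- 24 / 36
  expect_gte(cv$mean_accuracy, majority + 0.10)
})
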