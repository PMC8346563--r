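test_that("single pixels and separated blocks become tight objects", {
  m <- matrix(0, 10, 12)
  m[6, 8] <- 1  # row 6, col 8 -> 0-based (x=7, y=5)
  o <- mask_to_objects(m)
  expect_equal(nrow(o), 1)
  expect_equal(unlist(o[, c("x0", "y0", "x1", "y1")]),
               c(x0 = 7, y0 = 5, x1 = 8, y1 = 6))
  expect_equal(o$pixel_count, 1L)

  m2 <- matrix(0, 20, 20)
  m2[2:4, 2:4] <- 1
  m2[10:12, 14:16] <- 1
  o2 <- mask_to_objects(m2)
  expect_equal(nrow(o2), 2)
  expect_equal(sort(o2$pixel_count), c(9L, 9L))
})

test_that("diagonal contact joins under 8- but not 4-connectivity", {
  m <- matrix(0, 6, 6)
  m[2, 2] <- 1; m[3, 3] <- 1
  expect_equal(nrow(mask_to_objects(m, connectivity = 8)), 1)
  expect_equal(nrow(mask_to_objects(m, connectivity = 4)), 2)
  expect_error(mask_to_objects(matrix(2, 3, 3)), "binary")
})

test_that("component extraction agrees with a flood-fill oracle on random masks", {
  set.seed(100)
  for (rep in 1:25) {
    h <- sample(8:64, 1); w <- sample(8:64, 1)
    m <- matrix(rbinom(h * w, 1, runif(1, 0.05, 0.4)), h, w)
    for (conn in c(4, 8)) {
      got <- mask_to_objects(m, connectivity = conn)
      want <- oracle_objects(flood_fill_components(m, conn))
      expect_equal(nrow(got), nrow(want))
      # match on sorted (box, count) signatures; component ids may differ
      sig <- function(d) do.call(paste,
        c(d[order(d$x0, d$y0, d$x1, d$y1, d$pixel_count),
            c("x0", "y0", "x1", "y1", "pixel_count")], sep = "/"))
      expect_equal(sig(as.data.frame(got)), sig(want))
      expect_equal(sum(got$pixel_count), sum(m))
    }
  }
})

test_that("patches are labelled by box intersection with clipping", {
  obj <- tibble::tibble(component_id = 1:2,
                        x0 = c(10, 300), y0 = c(10, 100),
                        x1 = c(30, 340), y1 = c(25, 130),
                        pixel_count = c(100, 400))
  p <- patch_row(blob_patch(), ox = 0, oy = 0)
  lp <- label_patch(obj, p)
  expect_equal(lp$label, "exudate")
  expect_equal(nrow(lp$local_boxes), 1)
  expect_equal(unlist(lp$local_boxes), c(x0 = 10, y0 = 10, x1 = 30, y1 = 25))
  # straddling object clipped to positive area, translated
  p2 <- patch_row(blob_patch(), ox = 224, oy = 0)
  lp2 <- label_patch(obj, p2)
  expect_equal(lp2$label, "exudate")
  expect_equal(unlist(lp2$local_boxes), c(x0 = 76, y0 = 100, x1 = 116, y1 = 130))
  # no objects
  lp3 <- label_patch(obj[0, ], p)
  expect_equal(lp3$label, "non_exudate")
  expect_equal(nrow(lp3$local_boxes), 0)
})

test_that("black fraction counts max-channel-dark pixels", {
  z <- array(0, dim = c(8, 8, 3))
  expect_equal(black_fraction(z), 1)
  bright <- array(100, dim = c(8, 8, 3))
  expect_equal(black_fraction(bright), 0)
  half <- bright; half[, 1:4, ] <- 0
  expect_equal(black_fraction(half), 0.5)
  # a single bright channel rescues a pixel
  one <- z; one[, , 2] <- 50
  expect_equal(black_fraction(one), 0)
})

test_that("consensus mask implements the expert quorum", {
  base <- matrix(0, 4, 4)
  m1 <- base; m1[1, 1] <- 1; m1[2, 2] <- 1
  m2 <- base; m2[1, 1] <- 1; m2[2, 2] <- 1
  m3 <- base; m3[1, 1] <- 1
  m4 <- base
  cm <- consensus_mask(list(m1, m2, m3, m4), quorum = 0.75)
  expect_equal(cm[1, 1], 1L)  # 3 of 4 experts
  expect_equal(cm[2, 2], 0L)  # 2 of 4 experts
  expect_equal(consensus_mask(list(m1)), (m1 != 0) * 1L)  # identity
  expect_error(consensus_mask(list(m1, matrix(0, 3, 3))), "shape")
})

test_that("SVM set assembly enforces the 2:1 ratio, black rules and determinism", {
  mk_pool <- function(n, id, black = 0) {
    rows <- lapply(seq_len(n), function(i) {
      px <- array(100 + i, dim = c(16, 16, 3))
      if (black > 0) px[, seq_len(ceiling(16 * black)), ] <- 0
      patch_row(px, id = paste0(id, i))
    })
    dplyr::bind_rows(rows)
  }
  pos <- mk_pool(10, "p")
  dr <- mk_pool(15, "d")
  he <- mk_pool(15, "h")
  out <- assemble_svm_dataset(pos, dr, he, seed = 2)
  expect_equal(nrow(out), 10 + 20 + 4)
  expect_equal(sum(out$label == "exudate"), 10)
  expect_equal(sum(out$label == "non_exudate"), 24)
  expect_equal(sum(out$provenance == "black"), 4)
  expect_true(all(vapply(out$pixels[out$provenance == "black"],
                         function(p) all(p == 0), logical(1))))
  # half the sampled negatives from each pool
  expect_equal(sum(grepl("^d", out$source_id)), 10)
  expect_equal(sum(grepl("^h", out$source_id)), 10)
  # determinism
  expect_identical(assemble_svm_dataset(pos, dr, he, seed = 2)$source_id,
                   out$source_id)
  # negatives beyond the black cap are never sampled
  dark <- mk_pool(30, "x", black = 0.4)  # > 1/3 black
  out2 <- assemble_svm_dataset(pos, mk_pool(25, "d"), dark, seed = 3)
  expect_false(any(grepl("^x", out2$source_id)))
  # and they do not count toward sufficiency
  expect_error(assemble_svm_dataset(pos, dr[1:3, ], dark, seed = 1),
               "insufficient")
  expect_error(assemble_svm_dataset(pos[0, ], dr, he), "no positive")
})

test_that("fold construction reproduces the stratified size multisets", {
  f <- make_folds(paste0("p", 1:47), paste0("n", 1:35), k = 5, seed = 10)
  pos_sizes <- sort(table(f$fold[f$label == "exudates"]), decreasing = TRUE)
  neg_sizes <- table(f$fold[f$label == "healthy"])
  expect_equal(as.integer(pos_sizes), c(10, 10, 9, 9, 9))
  expect_equal(as.integer(neg_sizes), rep(7, 5))
  # partition: every id exactly once
  expect_setequal(f$image_id, c(paste0("p", 1:47), paste0("n", 1:35)))
  expect_equal(anyDuplicated(f$image_id), 0)
  # determinism
  expect_identical(make_folds(paste0("p", 1:47), paste0("n", 1:35),
                              k = 5, seed = 10), f)
  # degenerate: one id per fold
  f2 <- make_folds(paste0("p", 1:5), character(), k = 5, seed = 1)
  expect_equal(as.integer(table(f2$fold)), rep(1, 5))
  expect_error(make_folds(paste0("p", 1:3), character(), k = 5), "folds")
})
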