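# Connected-component labelling on the pixel adjacency graph. Returns an
# integer matrix of component labels (0 = background).
mask_components <- function(mask, connectivity = 8) {
  if (!connectivity %in% c(4, 8)) abort("`connectivity` must be 4 or 8")
  h <- nrow(mask); w <- ncol(mask)
  on <- which(mask != 0)
  labels <- matrix(0L, h, w)
  if (length(on) == 0) return(labels)
  r <- ((on - 1) %% h) + 1
  c <- ((on - 1) %/% h) + 1
  shifts <- list(c(0L, 1L), c(1L, 0L))                    # E, S
  if (connectivity == 8) shifts <- c(shifts, list(c(1L, 1L), c(-1L, 1L)))  # SE, NE
  is_on <- matrix(FALSE, h, w); is_on[on] <- TRUE
  # edges as positions within `on`, so vertex ids stay plain integers
  edges <- map(shifts, function(s) {
    r2 <- r + s[1]; c2 <- c + s[2]
    ok <- r2 >= 1 & r2 <= h & c2 >= 1 & c2 <= w
    ok[ok] <- is_on[cbind(r2[ok], c2[ok])]
    if (!any(ok)) return(NULL)
    nb <- (c2[ok] - 1) * h + r2[ok]
    cbind(which(ok), match(nb, on))
  })
  edges <- do.call(rbind, edges[!map_lgl(edges, is.null)])
  g <- igraph::make_graph(
    edges = if (is.null(edges)) integer() else as.vector(t(edges)),
    n = length(on), directed = FALSE)
  comp <- igraph::components(g)
  labels[on] <- comp$membership
  labels
}

#' Convert a binary mask into exudate objects
#'
#' Each connected component of the mask is one object (one lesion): lesions
#' are defined as marked regions not connected to any other marked region.
#' Every object carries the tight axis-aligned bounding box of its component
#' and its pixel count.
#'
#' @param mask Binary `H x W` matrix (0/1 or logical).
#' @param connectivity Pixel adjacency: 8 (default; diagonal contact joins
#'   components) or 4.
#' @return Tibble with columns `component_id`, `x0`, `y0`, `x1`, `y1`
#'   (0-based half-open) and `pixel_count`, ordered by `component_id`.
#' @examples
#' m <- matrix(0, 8, 8); m[3, 5] <- 1
#' mask_to_objects(m)  # one 1x1 object at (4, 2)
#' @export
mask_to_objects <- function(mask, connectivity = 8) {
  if (!is.matrix(mask) && !(is.array(mask) && length(dim(mask)) == 2)) {
    abort("`mask` must be a matrix")
  }
  vals <- unique(as.vector(mask))
  if (!all(vals %in% c(0, 1, TRUE, FALSE))) abort("`mask` must be binary")
  labels <- mask_components(mask, connectivity)
  k <- max(labels)
  if (k == 0) {
    return(tibble(component_id = integer(), x0 = numeric(), y0 = numeric(),
                  x1 = numeric(), y1 = numeric(), pixel_count = integer()))
  }
  h <- nrow(mask)
  idx <- which(labels > 0)
  comp <- labels[idx]
  r <- ((idx - 1) %% h)        # 0-based row = y
  c <- ((idx - 1) %/% h)       # 0-based col = x
  tibble(component_id = comp, x = c, y = r) |>
    group_by(.data$component_id) |>
    summarise(x0 = min(.data$x), y0 = min(.data$y),
              x1 = max(.data$x) + 1, y1 = max(.data$y) + 1,
              pixel_count = n(), .groups = "drop") |>
    arrange(.data$component_id)
}

#' Label a patch by ground-truth object intersection
#'
#' A patch is labelled `"exudate"` when at least one object's bounding box
#' intersects the patch window by at least one pixel; the intersections are
#' returned clipped and translated into patch-local coordinates.
#'
#' @param objects Object tibble from [mask_to_objects()] in padded-image
#'   coordinates.
#' @param patch One-row patch tibble (needs `origin_x`, `origin_y`).
#' @param tile Patch side in pixels.
#' @return List with `label` (`"exudate"` / `"non_exudate"`) and
#'   `local_boxes` (box tibble in patch coordinates).
#' @export
label_patch <- function(objects, patch, tile = 224) {
  ox <- patch$origin_x; oy <- patch$origin_y
  if (nrow(objects) == 0) {
    return(list(label = "non_exudate", local_boxes = boxes_tbl()))
  }
  ix0 <- pmax(objects$x0, ox); iy0 <- pmax(objects$y0, oy)
  ix1 <- pmin(objects$x1, ox + tile); iy1 <- pmin(objects$y1, oy + tile)
  keep <- ix0 < ix1 & iy0 < iy1
  if (!any(keep)) {
    return(list(label = "non_exudate", local_boxes = boxes_tbl()))
  }
  list(label = "exudate",
       local_boxes = boxes_tbl(ix0[keep] - ox, iy0[keep] - oy,
                               ix1[keep] - ox, iy1[keep] - oy))
}

#' Label every patch in a manifest
#'
#' @param patches Patch tibble.
#' @param objects Object tibble in padded-image coordinates.
#' @inheritParams label_patch
#' @return `patches` with added columns `label` and `boxes` (list of
#'   patch-local box tibbles).
#' @export
label_patches <- function(patches, objects, tile = 224) {
  lab <- map(seq_len(nrow(patches)),
             function(i) label_patch(objects, patches[i, ], tile))
  patches$label <- map_chr(lab, "label")
  patches$boxes <- map(lab, "local_boxes")
  patches
}

#' @importFrom purrr map_chr
NULL

#' Fraction of black pixels in a patch
#'
#' A pixel counts as black when its maximum channel intensity is at or below
#' `black_threshold`.
#'
#' @param pixels Patch pixel array (`H x W x 3`).
#' @param black_threshold Intensity cutoff on the 0-255 scale.
#' @return Fraction in `[0, 1]`.
#' @export
black_fraction <- function(pixels, black_threshold = 10) {
  validate_image(pixels, "pixels")
  mean(channel_max(pixels) <= black_threshold)
}

#' Fuse multi-expert masks by quorum
#'
#' A pixel is on in the consensus mask when at least
#' `ceiling(quorum * n_experts)` experts marked it — with the default 0.75
#' quorum and four experts, at least three of four.
#'
#' @param masks List of binary matrices of identical shape, one per expert.
#' @param quorum Required fraction of experts.
#' @return Binary matrix.
#' @export
consensus_mask <- function(masks, quorum = 0.75) {
  stopifnot(length(masks) >= 1)
  stop_if_not_scalar_frac(quorum, "quorum")
  d <- dim(masks[[1]])
  if (!all(map_lgl(masks, function(m) identical(dim(m), d)))) {
    abort("all expert masks must have the same shape")
  }
  need <- ceiling(quorum * length(masks))
  acc <- Reduce(`+`, map(masks, function(m) (m != 0) * 1L))
  (acc >= need) * 1L
}

#' Assemble the SVM gate training set
#'
#' Combines all exudate patches with exactly twice as many randomly sampled
#' non-exudate patches, drawn without replacement from two pools — background
#' patches of images with lesions and patches of healthy images (half from
#' each when both pools suffice, the remainder from the larger pool). Any
#' candidate negative with more than `black_frac_max` black pixels is
#' excluded before sampling. Four synthetic pure-black patches are appended
#' so the classifier learns to handle border tiles.
#'
#' @param positives Patch tibble of exudate patches.
#' @param negatives_dr Patch tibble: lesion-free patches from images with
#'   lesions (diabetic-retinopathy background).
#' @param negatives_healthy Patch tibble: patches from healthy images.
#' @param black_threshold Intensity cutoff for the black-pixel rule.
#' @param black_frac_max Maximum allowed black fraction for sampled
#'   negatives (default 1/3).
#' @param seed Optional seed for reproducible sampling.
#' @return Patch tibble with a `label` column; `2 * nrow(positives)`
#'   negatives plus `nrow(positives)` positives plus 4 black patches.
#' @export
assemble_svm_dataset <- function(positives, negatives_dr, negatives_healthy,
                                 black_threshold = 10, black_frac_max = 1 / 3,
                                 seed = NULL) {
  if (nrow(positives) == 0) abort("no positive patches supplied")
  run <- function() {
    eligible <- function(pool) {
      if (nrow(pool) == 0) return(pool)
      keep <- map_lgl(pool$pixels,
                      function(px) black_fraction(px, black_threshold) <= black_frac_max)
      pool[keep, ]
    }
    dr <- eligible(negatives_dr)
    he <- eligible(negatives_healthy)
    need <- 2L * nrow(positives)
    avail <- nrow(dr) + nrow(he)
    if (avail < need) {
      abort(sprintf(paste0("insufficient eligible negative patches: need %d, ",
                           "have %d (%d background, %d healthy)"),
                    need, avail, nrow(dr), nrow(he)))
    }
    half <- need %/% 2L
    n_dr <- min(nrow(dr), max(half, need - nrow(he)))
    n_he <- need - n_dr
    pick <- function(pool, n) {
      if (n == 0) return(pool[0, ])
      pool[sample.int(nrow(pool), n), ]
    }
    negs <- bind_rows(pick(dr, n_dr), pick(he, n_he))
    tile <- dim(positives$pixels[[1]])[1]
    blacks <- new_patch_tbl(
      map(1:4, function(i) array(0, dim = c(tile, tile, 3))),
      rep(0L, 4), rep(0L, 4), rep("synthetic_black", 4), rep("black", 4))
    pos <- positives; pos$label <- "exudate"
    negs$label <- "non_exudate"
    blacks$label <- "non_exudate"
    bind_rows(pos, negs, blacks)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Build stratified cross-validation folds
#'
#' Partitions each label class into `k` near-equal folds: with 47 positives
#' and `k = 5` the fold sizes are two tens and three nines; 35 negatives
#' split into five sevens. Fold sizes within a class differ by at most one.
#'
#' @param positive_ids,negative_ids Character or integer vectors of image
#'   ids (either may be empty).
#' @param k Number of folds (`>= 2`).
#' @param seed Optional seed for a reproducible shuffle.
#' @return Tibble with columns `image_id`, `label` (`"exudates"` /
#'   `"healthy"`) and `fold` (1..k).
#' @export
make_folds <- function(positive_ids, negative_ids = character(), k = 5,
                       seed = NULL) {
  if (k < 2) abort("`k` must be at least 2")
  if (length(positive_ids) > 0 && k > length(positive_ids)) {
    abort("more folds than positive images")
  }
  if (length(negative_ids) > 0 && k > length(negative_ids)) {
    abort("more folds than negative images")
  }
  assign_class <- function(ids, label) {
    n <- length(ids)
    if (n == 0) return(tibble(image_id = ids, label = character(), fold = integer()))
    ids <- ids[sample.int(n)]
    base <- n %/% k; extra <- n %% k
    sizes <- rep(base, k) + c(rep(1L, extra), rep(0L, k - extra))
    tibble(image_id = ids, label = label,
           fold = rep(seq_len(k), times = sizes))
  }
  run <- function() bind_rows(assign_class(positive_ids, "exudates"),
                              assign_class(negative_ids, "healthy"))
  if (is.null(seed)) run() else with_seed(seed, run())
}
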