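#' Pad an image with black rows/columns to a tile multiple
#'
#' Appends black columns on the right and black rows at the bottom so that
#' both dimensions become the smallest multiples of `tile` at least as large
#' as the originals. The original content is never resized and stays anchored
#' at the upper-left corner, so pixel coordinates (and mask alignment) are
#' unchanged.
#'
#' @param image `H x W x 3` intensity array.
#' @param tile Tile side in pixels (default 224, the standard network input).
#' @return A `padded_image`: list with `pixels` (`H' x W' x 3`), `pad_right`,
#'   `pad_bottom` and `original_size = c(width, height)`.
#' @examples
#' p <- pad_to_multiple(array(100, dim = c(960, 1440, 3)))
#' dim(p$pixels)[1:2]  # 1120 1568
#' @export
pad_to_multiple <- function(image, tile = 224) {
  validate_image(image)
  stopifnot(tile >= 1)
  h <- dim(image)[1]; w <- dim(image)[2]
  h2 <- as.integer(ceiling(h / tile) * tile)
  w2 <- as.integer(ceiling(w / tile) * tile)
  out <- array(0, dim = c(h2, w2, 3))
  out[seq_len(h), seq_len(w), ] <- image
  structure(list(pixels = out, pad_right = w2 - w, pad_bottom = h2 - h,
                 original_size = c(width = w, height = h), tile = tile),
            class = "padded_image")
}

validate_padded <- function(padded) {
  if (!inherits(padded, "padded_image")) abort("expected a `padded_image`")
  d <- dim(padded$pixels)
  if (d[1] %% padded$tile != 0 || d[2] %% padded$tile != 0) {
    abort("padded image dimensions are not multiples of the tile size")
  }
  invisible(padded)
}

new_patch_tbl <- function(pixels, origin_x, origin_y, source_id, provenance) {
  tibble(source_id = source_id, origin_x = as.integer(origin_x),
         origin_y = as.integer(origin_y), provenance = provenance,
         pixels = pixels)
}

crop_patch <- function(pixels, ox, oy, tile) {
  pixels[(oy + 1):(oy + tile), (ox + 1):(ox + tile), , drop = FALSE]
}

#' Tile a padded image into a non-overlapping patch grid
#'
#' Cuts the padded image into `(W'/tile) x (H'/tile)` non-overlapping tiles
#' at stride `tile`, enumerated row-major (left to right, then top to
#' bottom). Together the tiles partition the padded image exactly.
#'
#' @param padded A [pad_to_multiple()] result.
#' @param source_id Identifier carried into the patch manifest.
#' @return A patch tibble with columns `source_id`, `origin_x`, `origin_y`
#'   (0-based offsets in padded-image coordinates), `provenance`
#'   (`"original"`), and `pixels` (list of `tile x tile x 3` arrays).
#' @export
tile_patches <- function(padded, source_id = "image") {
  validate_padded(padded)
  tile <- padded$tile
  d <- dim(padded$pixels)
  oy <- seq(0, d[1] - tile, by = tile)
  ox <- seq(0, d[2] - tile, by = tile)
  grid <- expand.grid(origin_x = ox, origin_y = oy)  # row-major: x fastest
  grid <- grid[order(grid$origin_y, grid$origin_x), ]
  px <- map2(grid$origin_x, grid$origin_y,
             function(x, y) crop_patch(padded$pixels, x, y, tile))
  new_patch_tbl(px, grid$origin_x, grid$origin_y, source_id, "original")
}

#' Extract shifted tiles for training-set augmentation
#'
#' Adds three extra tile grids whose starting positions are offset by
#' `stride` pixels horizontally, vertically, and in both directions
#' simultaneously, each stepping by the full tile size. Only windows that
#' fit entirely inside the padded image are kept, so a single-tile image
#' yields no shifted patches.
#'
#' @inheritParams tile_patches
#' @param stride Offset of the shifted grids in pixels (default 112, half a
#'   tile).
#' @return A patch tibble with `provenance = "shifted"`.
#' @export
shifted_tiles <- function(padded, stride = 112, source_id = "image") {
  validate_padded(padded)
  tile <- padded$tile
  if (stride <= 0 || stride >= tile) abort("`stride` must be in (0, tile)")
  d <- dim(padded$pixels)
  offsets <- list(c(stride, 0), c(0, stride), c(stride, stride))
  rows <- map(offsets, function(off) {
    ox <- if (off[1] > d[2] - tile) integer() else seq(off[1], d[2] - tile, by = tile)
    oy <- if (off[2] > d[1] - tile) integer() else seq(off[2], d[1] - tile, by = tile)
    if (length(ox) == 0 || length(oy) == 0) return(NULL)
    grid <- expand.grid(origin_x = ox, origin_y = oy)
    grid <- grid[order(grid$origin_y, grid$origin_x), ]
    px <- map2(grid$origin_x, grid$origin_y,
               function(x, y) crop_patch(padded$pixels, x, y, tile))
    new_patch_tbl(px, grid$origin_x, grid$origin_y, source_id, "shifted")
  })
  out <- list_rbind(rows[!map_lgl(rows, is.null)])
  if (is.null(out) || nrow(out) == 0) {
    return(new_patch_tbl(list(), integer(), integer(), character(), character()))
  }
  out
}

flip_pixels <- function(px, horizontal, vertical) {
  if (horizontal) px <- px[, rev(seq_len(dim(px)[2])), , drop = FALSE]
  if (vertical) px <- px[rev(seq_len(dim(px)[1])), , , drop = FALSE]
  px
}

#' Mirror patches along both axes
#'
#' Every input patch yields exactly three mirrored patches: the horizontal
#' flip, the vertical flip, and the flip along both axes. Origins and source
#' ids are inherited; each flip is an involution (applying it twice recovers
#' the input).
#'
#' @param patches A patch tibble.
#' @return A patch tibble with `3 * nrow(patches)` rows and
#'   `provenance = "mirrored"`.
#' @export
mirror_patches <- function(patches) {
  flips <- list(c(TRUE, FALSE), c(FALSE, TRUE), c(TRUE, TRUE))
  rows <- map(flips, function(f) {
    out <- patches
    out$pixels <- map(patches$pixels, flip_pixels, horizontal = f[1],
                      vertical = f[2])
    out$provenance <- "mirrored"
    out
  })
  list_rbind(rows)
}

#' Contrast/brightness jitter with black-background preservation
#'
#' Applies one random contrast gain and brightness offset per patch:
#' `out = clip(g * (p - mu) + mu + b * 255)` with `g ~ U[1 - max_frac,
#' 1 + max_frac]`, `b ~ U[-max_frac, max_frac]`, and `mu` the patch mean over
#' non-black pixels. Pixels at or below `black_threshold` (the black padding
#' and the background outside the fundus disc) are left exactly unchanged,
#' and outputs are clipped to `[0, 255]`. With `max_frac = 0` the operation
#' is the identity.
#'
#' @param patches A patch tibble.
#' @param max_frac Half-width of the jitter band (default 0.2, i.e. up to
#'   20% contrast/brightness variation).
#' @param black_threshold Intensity (0-255) at or below which a pixel counts
#'   as background (default 10; real photographs have near-black, not exactly
#'   zero, backgrounds).
#' @param seed Optional seed; when given, draws are reproducible without
#'   touching the caller's RNG stream.
#' @return A patch tibble with `provenance = "jittered"`.
#' @export
jitter_patches <- function(patches, max_frac = 0.2, black_threshold = 10,
                           seed = NULL) {
  stop_if_not_scalar_frac(max_frac, "max_frac")
  run <- function() {
    out <- patches
    out$pixels <- map(patches$pixels, jitter_one, max_frac = max_frac,
                      black_threshold = black_threshold)
    out$provenance <- "jittered"
    out
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

jitter_one <- function(px, max_frac, black_threshold) {
  g <- runif(1, 1 - max_frac, 1 + max_frac)
  b <- runif(1, -max_frac, max_frac)
  jitter_one_fixed(px, g, b, black_threshold)
}

# deterministic core: contrast gain g about the non-black mean, brightness
# offset b (fraction of full scale), black pixels untouched
jitter_one_fixed <- function(px, g, b, black_threshold) {
  black <- channel_max(px) <= black_threshold
  mu <- mean(px[rep(!black, 3)])
  if (!is.finite(mu)) mu <- 0
  out <- clip255(g * (px - mu) + mu + b * 255)
  keep <- array(rep(black, 3), dim = dim(px))
  out[keep] <- px[keep]
  out
}

#' Translate a patch-local box into full-image coordinates
#'
#' @param boxes Box tibble in patch-local coordinates (0-based half-open).
#' @param patch A one-row patch tibble (or any list with `origin_x`,
#'   `origin_y`).
#' @return Box tibble translated by the patch origin.
#' @export
to_image_coords <- function(boxes, patch) {
  validate_boxes(boxes)
  tile <- if (!is.null(patch$pixels)) dim(patch$pixels[[1]])[1] else 224
  if (nrow(boxes) > 0 &&
      (any(boxes$x1 > tile) || any(boxes$y1 > tile))) {
    abort("box lies outside the patch bounds")
  }
  mutate(boxes,
         x0 = .data$x0 + patch$origin_x, x1 = .data$x1 + patch$origin_x,
         y0 = .data$y0 + patch$origin_y, y1 = .data$y1 + patch$origin_y)
}

#' Training-set augmentation arithmetic
#'
#' Given the number of original tiles with lesions and the number of shifted
#' tiles with lesions, mirroring each of them along the horizontal, vertical
#' and both axes produces `3 * (n_original + n_shifted)` mirrored patches,
#' for a grand total of `4 * (n_original + n_shifted)` training patches.
#'
#' @param n_original,n_shifted Patch counts before mirroring.
#' @return One-row tibble with `original`, `shifted`, `mirrored`, `total`.
#' @examples
#' augmentation_counts(307, 882)  # mirrored 3567, total 4756
#' @export
augmentation_counts <- function(n_original, n_shifted) {
  stopifnot(n_original >= 0, n_shifted >= 0)
  mirrored <- 3 * (n_original + n_shifted)
  tibble(original = n_original, shifted = n_shifted, mirrored = mirrored,
         total = n_original + n_shifted + mirrored)
}

#' Write a patch manifest as CSV
#'
#' @param patches A patch tibble (optionally with a `label` column).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_patch_manifest <- function(patches, path) {
  cols <- intersect(c("source_id", "origin_x", "origin_y", "provenance",
                      "label"), names(patches))
  write.csv(as.data.frame(patches[, cols]), path, row.names = FALSE)
  invisible(path)
}
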