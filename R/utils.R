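#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange bind_rows bind_cols group_by
#'   summarise ungroup across n row_number left_join
#' @importFrom purrr map map_dbl map_int map_lgl map2 pmap imap list_rbind
#' @importFrom stats quantile median rnorm runif sd setNames predict
#' @importFrom utils head read.csv write.csv
NULL

# Run `expr` under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Derive a stage-specific seed from a global seed
#'
#' A single pipeline seed fans out to per-stage seeds so that stages are
#' reproducible in isolation. The result is always a valid 32-bit integer
#' seed.
#'
#' @param seed Integer global seed.
#' @param stage Character stage tag (e.g. `"synth"`, `"gate"`).
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) * 7919 + h * 104729 + 13) %% (2^31 - 1))
}

stop_if_not_scalar_frac <- function(x, name, max_open = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 ||
      (if (max_open) x >= 1 else x > 1)) {
    abort(sprintf("`%s` must be a single number in [0, 1%s]",
                  name, if (max_open) ")" else ""))
  }
}

# ---- bounding boxes ---------------------------------------------------------
# Boxes are 0-based, half-open: a box covers columns [x0, x1) and rows
# [y0, y1) of the image, so width = x1 - x0 with no +/-1 bookkeeping.

#' Construct a tibble of bounding boxes
#'
#' Boxes use 0-based, half-open pixel coordinates: `[x0, x1) x [y0, y1)`.
#'
#' @param x0,y0,x1,y1 Numeric vectors of box edges; `x1 > x0`, `y1 > y0`.
#' @return A tibble with columns `x0`, `y0`, `x1`, `y1`.
#' @export
boxes_tbl <- function(x0 = numeric(), y0 = numeric(),
                      x1 = numeric(), y1 = numeric()) {
  b <- tibble(x0 = as.numeric(x0), y0 = as.numeric(y0),
              x1 = as.numeric(x1), y1 = as.numeric(y1))
  validate_boxes(b)
  b
}

validate_boxes <- function(boxes, what = "boxes") {
  need <- c("x0", "y0", "x1", "y1")
  if (!is.data.frame(boxes) || !all(need %in% names(boxes))) {
    abort(sprintf("`%s` must be a data frame with columns x0, y0, x1, y1", what))
  }
  if (nrow(boxes) == 0) return(invisible(boxes))
  if (any(boxes$x1 <= boxes$x0) || any(boxes$y1 <= boxes$y0) ||
      any(boxes$x0 < 0) || any(boxes$y0 < 0)) {
    abort(sprintf("`%s` contains degenerate or negative boxes", what))
  }
  invisible(boxes)
}

box_area <- function(boxes) (boxes$x1 - boxes$x0) * (boxes$y1 - boxes$y0)

# Closed-form intersection area of one box against a tibble of boxes.
box_intersection_area <- function(box, boxes) {
  iw <- pmax(0, pmin(box$x1, boxes$x1) - pmax(box$x0, boxes$x0))
  ih <- pmax(0, pmin(box$y1, boxes$y1) - pmax(box$y0, boxes$y0))
  iw * ih
}

box_iou <- function(box, boxes) {
  inter <- box_intersection_area(box, boxes)
  uni <- box_area(box) + box_area(boxes) - inter
  ifelse(uni > 0, inter / uni, 0)
}

# ---- image helpers ----------------------------------------------------------
# Images are numeric arrays [height, width, 3] with intensities in [0, 255].

validate_image <- function(image, what = "image") {
  if (!is.array(image) || length(dim(image)) != 3 || dim(image)[3] != 3) {
    abort(sprintf("`%s` must be an H x W x 3 array", what))
  }
  if (dim(image)[1] < 1 || dim(image)[2] < 1) abort(sprintf("`%s` is empty", what))
  invisible(image)
}

# Per-pixel maximum across channels; used by the black-pixel rule.
channel_max <- function(image) {
  pmax(image[, , 1], image[, , 2], image[, , 3])
}

gray_intensity <- function(image) {
  (image[, , 1] + image[, , 2]) / 2
}

clip255 <- function(x) {
  x[x < 0] <- 0
  x[x > 255] <- 255
  x
}

# 3x3 box blur with edge replication; cheap smoothing for the reference
# detector's candidate map.
box_blur3 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  pad <- m[c(1, seq_len(h), h), c(1, seq_len(w), w)]
  acc <- matrix(0, h, w)
  for (dr in 0:2) for (dc in 0:2) {
    acc <- acc + pad[dr + seq_len(h), dc + seq_len(w)]
  }
  acc / 9
}

# ---- PNG I/O ----------------------------------------------------------------

#' Write an image or mask as PNG
#'
#' Intensities in `[0, 255]` are rescaled to the `[0, 1]` range PNG stores.
#'
#' @param image `H x W x 3` array (or `H x W` matrix for a mask).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(image, path) {
  png::writePNG(image / 255, path)
  invisible(path)
}

#' Read a PNG image into the 0-255 intensity convention
#'
#' @param path PNG file path.
#' @param mask If `TRUE`, return a binary `H x W` matrix (pixel on when
#'   intensity > 0.5 of full scale).
#' @return `H x W x 3` array in `[0, 255]`, or a binary matrix.
#' @export
read_image_png <- function(path, mask = FALSE) {
  x <- png::readPNG(path)
  if (mask) {
    if (length(dim(x)) == 3) x <- x[, , 1]
    return((x > 0.5) * 1L)
  }
  if (length(dim(x)) == 2) x <- array(rep(x, 3), dim = c(dim(x), 3))
  if (dim(x)[3] > 3) x <- x[, , 1:3]
  x * 255
}
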