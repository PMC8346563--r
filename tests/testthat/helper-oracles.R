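# Independent oracles, deliberately naive and separate from the package's
# code paths.

# Flood-fill connected-component labelling by breadth-first search.
flood_fill_components <- function(mask, connectivity = 8) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  nb <- if (connectivity == 8) {
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    cbind(c(-1, 0, 0, 1), c(0, -1, 1, 0))
  }
  k <- 0L
  for (r in seq_len(h)) for (c in seq_len(w)) {
    if (mask[r, c] != 0 && lab[r, c] == 0L) {
      k <- k + 1L
      queue <- list(c(r, c)); lab[r, c] <- k
      while (length(queue) > 0) {
        p <- queue[[1]]; queue <- queue[-1]
        for (j in seq_len(nrow(nb))) {
          rr <- p[1] + nb[j, 1]; cc <- p[2] + nb[j, 2]
          if (rr >= 1 && rr <= h && cc >= 1 && cc <= w &&
              mask[rr, cc] != 0 && lab[rr, cc] == 0L) {
            lab[rr, cc] <- k
            queue[[length(queue) + 1]] <- c(rr, cc)
          }
        }
      }
    }
  }
  lab
}

# Tight boxes + pixel counts from a label matrix, 0-based half-open coords.
oracle_objects <- function(lab) {
  k <- max(lab)
  out <- list()
  for (i in seq_len(k)) {
    idx <- which(lab == i, arr.ind = TRUE)
    out[[i]] <- data.frame(component_id = i,
                           x0 = min(idx[, 2]) - 1, y0 = min(idx[, 1]) - 1,
                           x1 = max(idx[, 2]), y1 = max(idx[, 1]),
                           pixel_count = nrow(idx))
  }
  if (k == 0) return(data.frame(component_id = integer(), x0 = numeric(),
                                y0 = numeric(), x1 = numeric(), y1 = numeric(),
                                pixel_count = integer()))
  do.call(rbind, out)
}

# Pixel-index set of a 0-based half-open box in an h x w image (1-based
# linear indices, column-major like R matrices).
box_pixel_set <- function(box, h) {
  rows <- (box$y0 + 1):box$y1
  cols <- (box$x0 + 1):box$x1
  as.vector(outer(rows, (cols - 1) * h, `+`))
}

# Brute-force exudate-level matcher: explicit pixel-set arithmetic.
oracle_match <- function(gt, det, shape, overlap_min = 0.2,
                         mode = "strict") {
  h <- shape[1]
  gt_sets <- lapply(seq_len(nrow(gt)), function(i) box_pixel_set(gt[i, ], h))
  det_sets <- lapply(seq_len(nrow(det)), function(j) box_pixel_set(det[j, ], h))
  found <- rep(FALSE, nrow(gt)); matched <- rep(FALSE, nrow(det))
  for (i in seq_along(gt_sets)) for (j in seq_along(det_sets)) {
    inter <- length(intersect(gt_sets[[i]], det_sets[[j]]))
    hit <- if (mode == "strict") {
      inter / length(gt_sets[[i]]) > overlap_min
    } else inter >= 1
    if (hit) {
      found[i] <- TRUE; matched[j] <- TRUE
    }
  }
  tp_set <- unique(unlist(gt_sets[found]))
  fn_set <- setdiff(unique(unlist(gt_sets[!found])), tp_set)
  fp_set <- setdiff(unique(unlist(det_sets[!matched])), union(tp_set, fn_set))
  list(tp = length(tp_set), fp = length(fp_set), fn = length(fn_set),
       tn = prod(shape) - length(tp_set) - length(fp_set) - length(fn_set),
       found = found, matched = matched)
}

# Random non-degenerate boxes inside an h x w scene.
random_boxes <- function(n, h, w, max_side = 16) {
  if (n == 0) {
    return(data.frame(x0 = numeric(), y0 = numeric(),
                      x1 = numeric(), y1 = numeric()))
  }
  x0 <- sample(0:(w - 2), n, replace = TRUE)
  y0 <- sample(0:(h - 2), n, replace = TRUE)
  x1 <- pmin(w, x0 + sample(1:max_side, n, replace = TRUE))
  y1 <- pmin(h, y0 + sample(1:max_side, n, replace = TRUE))
  data.frame(x0 = x0, y0 = y0, x1 = x1, y1 = y1)
}

# Brute-force soft-margin linear SVM: minimise 0.5*||w||^2 + C * sum(hinge)
# by multi-restart quasi-Newton optimisation; independent of libsvm.
oracle_linear_svm <- function(X, y, C = 1) {
  # y in {-1, +1}
  obj <- function(par) {
    w <- par[-length(par)]; b <- par[length(par)]
    f <- X %*% w + b
    0.5 * sum(w^2) + C * sum(pmax(0, 1 - y * f))
  }
  best <- NULL
  for (s in 1:8) {
    set.seed(s)
    par0 <- rnorm(ncol(X) + 1, sd = 0.5)
    fit <- optim(par0, obj, method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-12))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  list(w = best$par[-length(best$par)], b = best$par[length(best$par)],
       value = best$value)
}

# A flat test patch with optional bright blobs, for detector/gate tests.
blob_patch <- function(base = 120, blobs = list(), side = 224, noise = 0,
                       seed = 1) {
  set.seed(seed)
  g <- matrix(base, side, side)
  if (noise > 0) g <- g + matrix(rnorm(side^2, sd = noise), side, side)
  for (b in blobs) {
    xs <- matrix(rep(seq_len(side) - 1, each = side), side, side)
    ys <- matrix(rep(seq_len(side) - 1, times = side), side, side)
    d <- sqrt((xs - b$x)^2 + (ys - b$y)^2)
    g[d <= b$r] <- g[d <= b$r] + b$gain
  }
  g[g < 0] <- 0; g[g > 255] <- 255
  array(rep(g, 3), dim = c(side, side, 3))
}

patch_row <- function(pixels, ox = 0, oy = 0, id = "t",
                      provenance = "original") {
  tibble::tibble(source_id = id, origin_x = as.integer(ox),
                 origin_y = as.integer(oy), provenance = provenance,
                 pixels = list(pixels))
}
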