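#' Feature extractors for the patch gate
#'
#' A feature extractor is a pluggable contract: it maps a `224 x 224 x 3`
#' patch to a fixed-length numeric vector, deterministically. Two extractors
#' ship with the package:
#'
#' * `toy_extractor()` — per-channel intensity histograms, gradient-magnitude
#'   statistics, and bright-blob contrast statistics (upper intensity
#'   quantiles and the fractions of pixels exceeding the patch median by
#'   fixed contrasts, which respond directly to compact bright lesions);
#'   small (default 36-dimensional), fast, and fully closed-form, used
#'   throughout the test suite.
#' * `pooled_embedding_extractor()` — a deterministic seeded random-feature
#'   embedding with the same 2048-length interface as the final average-pool
#'   layer of the standard 50-layer residual backbone: patches are block-mean
#'   pooled to 16x16 per channel, then expanded through a fixed Gaussian
#'   random projection with a rectifier. It is a random-feature embedding,
#'   not a trained network, but honours the 2048-length feature contract the
#'   gate expects from that backbone.
#'
#' @param bins Histogram bins per channel for the toy extractor.
#' @param grad_threshold Gradient magnitude counted as "edge" in the edge
#'   fraction statistic.
#' @return An object of class `exu_extractor` with fields `id`, `dim` and
#'   `fn`.
#' @export
toy_extractor <- function(bins = 8, grad_threshold = 20) {
  stopifnot(bins >= 2)
  ex <- list(
    id = sprintf("toy_hist_grad_b%d", bins),
    dim = 3L * bins + 12L,
    fn = function(px) {
      hist1 <- function(v) {
        cut_idx <- pmin(bins, pmax(1, ceiling(as.vector(v) / (255 / bins))))
        cut_idx[as.vector(v) <= 0] <- 1
        tabulate(cut_idx, nbins = bins) / length(v)
      }
      g <- gray_intensity(px)
      gx <- cbind(g[, -1] - g[, -ncol(g)], 0)
      gy <- rbind(g[-1, ] - g[-nrow(g), ], 0)
      gm <- sqrt(gx^2 + gy^2)
      med <- stats::median(g)
      c(hist1(px[, , 1]), hist1(px[, , 2]), hist1(px[, , 3]),
        mean(gm), stats::sd(as.vector(gm)), max(gm),
        stats::median(gm), as.numeric(quantile(gm, 0.9)),
        mean(gm > grad_threshold),
        # bright-blob contrast statistics (scaled to [0, ~1])
        as.numeric(quantile(g, c(0.9, 0.99, 0.999))) / 255, max(g) / 255,
        mean(g > med + 25), mean(g > med + 50))
    })
  class(ex) <- "exu_extractor"
  ex
}

#' @rdname toy_extractor
#' @param dim Output embedding length (default 2048).
#' @param seed Seed fixing the random projection; the extractor is
#'   deterministic given `dim` and `seed`.
#' @export
pooled_embedding_extractor <- function(dim = 2048, seed = 7) {
  stopifnot(dim >= 1)
  pool_side <- 16L
  in_dim <- pool_side^2 * 3L
  proj <- with_seed(seed, matrix(rnorm(in_dim * dim, sd = 1 / sqrt(in_dim)),
                                 in_dim, dim))
  ex <- list(
    id = sprintf("pooled_rp_%d_s%d", dim, seed),
    dim = as.integer(dim),
    fn = function(px) {
      side <- base::dim(px)[1]
      blk <- side / pool_side
      pooled <- vapply(1:3, function(ch) {
        m <- px[, , ch]
        # block-mean pool to pool_side x pool_side
        m2 <- matrix(0, pool_side, pool_side)
        for (i in seq_len(pool_side)) for (j in seq_len(pool_side)) {
          m2[i, j] <- mean(m[((i - 1) * blk + 1):(i * blk),
                             ((j - 1) * blk + 1):(j * blk)])
        }
        as.vector(m2)
      }, numeric(pool_side^2))
      z <- as.vector(as.vector(pooled) %*% proj) / 255
      pmax(z, 0)
    })
  class(ex) <- "exu_extractor"
  ex
}

#' @export
print.exu_extractor <- function(x, ...) {
  cat(sprintf("<exu_extractor> id=%s, dim=%d\n", x$id, x$dim))
  invisible(x)
}

#' Extract fixed-length features from patches
#'
#' @param patches Patch tibble (or a single `H x W x 3` array).
#' @param extractor An `exu_extractor`.
#' @return Numeric matrix with one row per patch and `extractor$dim`
#'   columns; the extractor id is attached as attribute `"extractor_id"`.
#' @export
extract_features <- function(patches, extractor) {
  stopifnot(inherits(extractor, "exu_extractor"))
  px_list <- if (is.data.frame(patches)) patches$pixels else list(patches)
  feats <- map(px_list, function(px) {
    validate_image(px, "patch pixels")
    if (dim(px)[1] != 224 || dim(px)[2] != 224) {
      abort("patches must be 224 x 224 x 3")
    }
    v <- extractor$fn(px)
    if (length(v) != extractor$dim || !all(is.finite(v))) {
      abort("extractor returned a vector of wrong length or non-finite values")
    }
    v
  })
  out <- do.call(rbind, feats)
  attr(out, "extractor_id") <- extractor$id
  out
}

#' Train the linear SVM patch gate
#'
#' Fits a maximum-margin linear separator (hinge loss, penalty `C`) on patch
#' features, labelling patches as containing exudates or not. Features are
#' used unscaled. The returned model stores the primal weight vector and
#' bias, so classification is a plain dot product.
#'
#' @param features Numeric feature matrix (rows = patches), e.g. from
#'   [extract_features()].
#' @param labels Vector coercible to the two classes `"exudate"` /
#'   `"non_exudate"` (logical `TRUE` means exudate); both classes must be
#'   present.
#' @param C Soft-margin penalty (default 1).
#' @return An `exu_gate` model: `weights`, `bias`, `C`, `extractor_id`,
#'   `n_support`.
#' @export
train_gate <- function(features, labels, C = 1) {
  features <- as.matrix(features)
  y <- normalise_gate_labels(labels)
  if (length(unique(y)) < 2) abort("both classes must be present to train the gate")
  if (nrow(features) != length(y)) abort("features and labels differ in length")
  fit <- e1071::svm(x = features, y = factor(y, levels = c("non_exudate", "exudate")),
                    kernel = "linear", cost = C, scale = FALSE)
  w <- drop(crossprod(fit$coefs, fit$SV))
  b <- -fit$rho
  # orient the decision function so positive margin means "exudate"
  dv <- drop(features %*% w) + b
  pred <- as.character(predict(fit, features))
  agree <- mean((dv >= 0) == (pred == "exudate"))
  if (agree < 0.5) {
    w <- -w; b <- -b
  }
  structure(list(weights = as.numeric(w), bias = as.numeric(b), C = C,
                 extractor_id = attr(features, "extractor_id") %||% "unknown",
                 n_support = nrow(fit$SV)),
            class = "exu_gate")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

normalise_gate_labels <- function(labels) {
  if (is.logical(labels)) return(ifelse(labels, "exudate", "non_exudate"))
  lab <- as.character(labels)
  if (!all(lab %in% c("exudate", "non_exudate"))) {
    abort('labels must be "exudate"/"non_exudate" (or logical)')
  }
  lab
}

#' @export
print.exu_gate <- function(x, ...) {
  cat(sprintf("<exu_gate> linear SVM, %d features, C=%g, %d support vectors\n",
              length(x$weights), x$C, x$n_support))
  invisible(x)
}

#' Classify patch features with the gate
#'
#' The margin is `weights . x + bias`; a patch is labelled `"exudate"` when
#' the margin is at or above zero — the boundary is assigned to the positive
#' class so the pre-scan errs toward sending patches on to the detector.
#'
#' @param model An `exu_gate`.
#' @param features Feature matrix (rows = patches) or a single vector.
#' @return Tibble with columns `margin` and `label`.
#' @export
gate_classify <- function(model, features) {
  stopifnot(inherits(model, "exu_gate"))
  if (is.null(dim(features))) features <- matrix(features, nrow = 1)
  if (ncol(features) != length(model$weights)) {
    abort("feature length does not match the gate model")
  }
  margin <- drop(features %*% model$weights) + model$bias
  tibble(margin = as.numeric(margin),
         label = ifelse(margin >= 0, "exudate", "non_exudate"))
}

#' Filter patches through the gate
#'
#' Keeps, in their original order, exactly the patches the gate classifies
#' as containing exudates. Filtering is idempotent.
#'
#' @param patches Patch tibble.
#' @param model An `exu_gate`.
#' @param extractor The `exu_extractor` matching the model.
#' @return The retained subset of `patches`, with a `gate_margin` column.
#' @export
gate_filter <- function(patches, model, extractor) {
  if (nrow(patches) == 0) return(patches)
  cls <- gate_classify(model, extract_features(patches, extractor))
  out <- patches[cls$label == "exudate", ]
  out$gate_margin <- cls$margin[cls$label == "exudate"]
  out
}

#' Cross-validated gate accuracy
#'
#' For each fold, trains the gate on the other `k - 1` folds and reports the
#' fraction of correctly classified patches in the held-out fold, plus the
#' mean over folds.
#'
#' @param features Feature matrix for all patches.
#' @param labels Class labels (see [train_gate()]).
#' @param folds Integer fold assignment per patch (values 1..k, `k >= 2`).
#' @param C Soft-margin penalty.
#' @return An `exu_gate_cv`: list with `per_fold` (tibble `fold`, `n`,
#'   `accuracy`, `single_class` flag for one-class validation folds) and
#'   `mean_accuracy`.
#' @export
gate_cv_accuracy <- function(features, labels, folds, C = 1) {
  y <- normalise_gate_labels(labels)
  folds <- as.integer(folds)
  ks <- sort(unique(folds))
  if (length(ks) < 2) abort("at least two folds are required")
  per <- map(ks, function(k) {
    tr <- folds != k
    model <- train_gate(features[tr, , drop = FALSE], y[tr], C = C)
    pred <- gate_classify(model, features[!tr, , drop = FALSE])$label
    tibble(fold = k, n = sum(!tr),
           accuracy = mean(pred == y[!tr]),
           single_class = length(unique(y[!tr])) < 2)
  })
  per <- list_rbind(per)
  structure(list(per_fold = per, mean_accuracy = mean(per$accuracy), C = C),
            class = "exu_gate_cv")
}

#' @export
print.exu_gate_cv <- function(x, ...) {
  cat(sprintf("<exu_gate_cv> %d folds, mean accuracy %.3f\n",
              nrow(x$per_fold), x$mean_accuracy))
  invisible(x)
}
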