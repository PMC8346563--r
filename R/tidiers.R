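#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy the linear SVM gate
#'
#' @param x An `exu_gate`.
#' @param ... Unused.
#' @return Tibble with one row per model term (`bias` then `w1`, `w2`, ...).
#' @export
tidy.exu_gate <- function(x, ...) {
  tibble(term = c("bias", paste0("w", seq_along(x$weights))),
         estimate = c(x$bias, x$weights))
}

#' @rdname tidy.exu_gate
#' @return `glance()`: one-row tibble with `n_features`, `C`, `n_support`,
#'   `extractor_id`.
#' @export
glance.exu_gate <- function(x, ...) {
  tibble(n_features = length(x$weights), C = x$C, n_support = x$n_support,
         extractor_id = x$extractor_id)
}

#' Tidy cross-validated gate accuracies
#'
#' @param x An `exu_gate_cv`.
#' @param ... Unused.
#' @return `tidy()`: the per-fold accuracy tibble; `glance()`: one row with
#'   the fold count and mean accuracy.
#' @export
tidy.exu_gate_cv <- function(x, ...) x$per_fold

#' @rdname tidy.exu_gate_cv
#' @export
glance.exu_gate_cv <- function(x, ...) {
  tibble(k = nrow(x$per_fold), mean_accuracy = x$mean_accuracy, C = x$C)
}

#' Tidy a trained detector
#'
#' @param x An `exu_detector`.
#' @param ... Unused.
#' @return `tidy()`: parameter tibble; `glance()`: one row echoing the
#'   training configuration (learning rate, mini-batch, epochs, backend).
#' @export
tidy.exu_detector <- function(x, ...) {
  tibble(term = names(x$params), estimate = as.numeric(unlist(x$params)))
}

#' @rdname tidy.exu_detector
#' @export
glance.exu_detector <- function(x, ...) {
  tibble(backend = x$backend,
         learning_rate = x$config$learning_rate,
         mini_batch = x$config$mini_batch,
         epochs = x$config$epochs,
         n_anchors = nrow(x$anchors))
}

#' Tidy an exudate-level match
#'
#' @param x An `exu_match`.
#' @param ... Unused.
#' @return `tidy()`: per-ground-truth-object status tibble; `glance()`: the
#'   pixel tallies with the derived metric set.
#' @export
tidy.exu_match <- function(x, ...) x$gt_status

#' @rdname tidy.exu_match
#' @export
glance.exu_match <- function(x, ...) {
  bind_cols(x$counts, compute_metrics(x$counts))
}

#' Tidy a cross-validated pipeline run
#'
#' @param x An `exu_cv_run`.
#' @param ... Unused.
#' @return `tidy()`: per-fold metrics at both levels (long layout);
#'   `glance()`: one row with the variant switches and patch bookkeeping.
#' @export
tidy.exu_cv_run <- function(x, ...) {
  bind_rows(mutate(x$exudate_folds, level = "exudate"),
            mutate(x$image_folds, level = "image"))
}

#' @rdname tidy.exu_cv_run
#' @export
glance.exu_cv_run <- function(x, ...) {
  tibble(use_gate = x$use_gate, use_jitter = x$use_jitter,
         k = nrow(x$exudate_folds), n_patches = x$n_patches,
         n_gated_out = x$n_gated_out,
         exudate_f1 = x$exudate_summary$mean[x$exudate_summary$metric == "f1"],
         image_f1 = x$image_summary$mean[x$image_summary$metric == "f1"])
}
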