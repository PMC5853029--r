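#' Select the binary in/out-of-focus threshold on a validation split
#'
#' Reproduces the thresholded binary protocol: a random `validation_fraction`
#' of the images is set aside, and the threshold maximizing the F-score on
#' that subset is chosen from the midpoints between consecutive sorted
#' validation scores (plus one candidate below the minimum and one above the
#' maximum). Images with score `>= threshold` are called positive
#' (out-of-focus for level-like scores). Ties are broken toward the lowest
#' threshold.
#'
#' @param scores Numeric per-image scores (higher = more defocused by
#'   default).
#' @param labels Binary ground truth (0 = in focus, 1 = out of focus).
#' @param validation_fraction Fraction used for threshold selection
#'   (default 0.1). Use 1 to select on all data.
#' @param seed Integer seed for the random split.
#' @return List of class `threshold_selection`: `threshold`,
#'   `validation_f_score`, `validation_idx`, `seed`.
#' @export
select_threshold <- function(scores, labels, validation_fraction = 0.1,
                             seed = 1L) {
  stopifnot(length(scores) == length(labels),
            validation_fraction > 0, validation_fraction <= 1)
  labels <- as.integer(labels)
  n <- length(scores)
  n_val <- max(1L, round(validation_fraction * n))
  idx <- if (n_val >= n) seq_len(n) else
    withr::with_seed(seed, sort(sample.int(n, n_val)))
  sv <- scores[idx]; lv <- labels[idx]
  if (length(unique(lv)) < 2) {
    stop("validation split contains a single class; try another seed",
         call. = FALSE)
  }
  cand <- threshold_candidates(sv)
  f <- vapply(cand, function(th) f_score_at(sv, lv, th), numeric(1))
  best <- cand[which.max(f)] # which.max takes the first (lowest) on ties
  structure(list(threshold = best, validation_f_score = max(f),
                 validation_idx = idx, seed = seed),
            class = "threshold_selection")
}

threshold_candidates <- function(scores) {
  s <- sort(unique(scores))
  if (length(s) == 1) return(c(s - 1, s, s + 1))
  mid <- (s[-1] + s[-length(s)]) / 2
  c(min(s) - 1, sort(c(s, mid)), max(s) + 1)
}

f_score_at <- function(scores, labels, threshold) {
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  if (tp == 0) return(0)
  precision <- tp / (tp + fp)
  recall <- tp / (tp + fn)
  2 * precision * recall / (precision + recall)
}

#' Evaluate the binary in/out-of-focus task at a fixed threshold
#'
#' Applies a previously chosen threshold to the test images and reports
#' precision, recall and their harmonic mean (the F-score). Pass the output
#' of [select_threshold()] to evaluate on the complementary 90% test split
#' automatically, or a bare numeric threshold to evaluate on everything.
#'
#' @param scores Numeric per-image scores.
#' @param labels Binary ground truth (1 = out of focus).
#' @param threshold A `threshold_selection` or a finite number. Scores
#'   `>= threshold` are called out-of-focus.
#' @return List of class `binary_eval_result`: `chosen_threshold`,
#'   `precision`, `recall`, `f_score`, `n_test`, `no_positive_calls` flag,
#'   `split_seed`.
#' @export
binary_evaluate <- function(scores, labels, threshold) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  split_seed <- NA_integer_
  if (inherits(threshold, "threshold_selection")) {
    keep <- setdiff(seq_along(scores), threshold$validation_idx)
    split_seed <- threshold$seed
    scores <- scores[keep]; labels <- labels[keep]
    threshold <- threshold$threshold
  }
  if (!is.finite(threshold)) stop("threshold must be finite", call. = FALSE)
  if (length(scores) == 0) stop("empty test split", call. = FALSE)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  no_pos <- (tp + fp) == 0
  precision <- if (no_pos) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  structure(list(chosen_threshold = threshold, precision = precision,
                 recall = recall, f_score = f, n_test = length(scores),
                 no_positive_calls = no_pos, split_seed = split_seed),
            class = "binary_eval_result")
}

#' Reduce a whole-image prediction to a rankable defocus score
#'
#' The 11-class aggregate distribution is summarized as a scalar that orders
#' images by defocus: the expected level `sum(i * p_i)` by default, the
#' argmax level, or one minus the in-focus probability.
#'
#' @param image_pred A [aggregate_image()] result.
#' @param method One of `"expected"`, `"argmax"`, `"p_out"`.
#' @return Scalar score (higher = more defocused).
#' @export
model_binary_score <- function(image_pred,
                               method = c("expected", "argmax", "p_out")) {
  stopifnot(inherits(image_pred, "whole_image_prediction"))
  method <- match.arg(method)
  p <- image_pred$aggregate_distribution
  switch(method,
         expected = sum((seq_along(p) - 1) * p),
         argmax = as.numeric(image_pred$predicted_level),
         p_out = 1 - p[1])
}

#' Confusion matrix over defocus levels
#'
#' @param true_levels,predicted_levels Integer vectors of equal length,
#'   values in `0 .. n_levels - 1`.
#' @param n_levels Number of classes (default 11).
#' @return `n_levels x n_levels` integer matrix of counts; rows are true
#'   levels, columns predicted levels.
#' @export
confusion <- function(true_levels, predicted_levels, n_levels = 11L) {
  stopifnot(length(true_levels) == length(predicted_levels))
  if (any(true_levels < 0 | true_levels >= n_levels |
            predicted_levels < 0 | predicted_levels >= n_levels)) {
    stop("levels out of range", call. = FALSE)
  }
  lv <- 0:(n_levels - 1L)
  cm <- table(factor(true_levels, levels = lv),
              factor(predicted_levels, levels = lv))
  m <- matrix(as.integer(cm), n_levels, n_levels,
              dimnames = list(true = lv, predicted = lv))
  m
}

#' Fraction of predictions within k levels of the truth
#'
#' @param cm Confusion matrix from [confusion()].
#' @param k Band half-width in levels (default 1: "within one level").
#' @return Fraction in `[0, 1]`.
#' @export
within_k_accuracy <- function(cm, k = 1L) {
  stopifnot(is.matrix(cm), nrow(cm) == ncol(cm))
  if (sum(cm) == 0) stop("empty confusion matrix", call. = FALSE)
  n <- nrow(cm)
  band <- abs(outer(seq_len(n), seq_len(n), "-")) <= k
  sum(cm[band]) / sum(cm)
}

#' Gain/offset robustness grid
#'
#' Re-evaluates a trained model on photometrically transformed copies of a
#' labeled test set: for every (gain, offset) cell each patch is mapped to
#' `clip(patch * gain + offset, 0, 65535)` before prediction, and a
#' confusion matrix is accumulated. The identity cell (gain 1, offset 0)
#' equals plain evaluation.
#'
#' @param model A trained [train_focus_model()] model.
#' @param test_set A [labeled_patch_set()].
#' @param gains Numeric vector of gains (should include 1).
#' @param offsets Numeric vector of offsets in counts (should include 0).
#' @param foreground_only Restrict to foreground patches (where focus is
#'   well-defined)? Default `TRUE`.
#' @return List of class `robustness_grid`: `confusions` (list of matrices
#'   indexed `g<gain>_o<offset>`), `within_one` (matrix gains x offsets),
#'   `gains`, `offsets`.
#' @export
robustness_grid <- function(model, test_set, gains = c(0.5, 1, 2),
                            offsets = c(0, 1000), foreground_only = TRUE) {
  stopifnot(inherits(model, "focus_model"),
            inherits(test_set, "labeled_patch_set"))
  keep <- if (foreground_only) which(test_set$foreground) else
    seq_along(test_set$labels)
  patches <- test_set$patches[, , keep, drop = FALSE]
  labels <- test_set$labels[keep]
  n_levels <- model$spec$n_levels
  confusions <- list()
  within_one <- matrix(NA_real_, length(gains), length(offsets),
                       dimnames = list(gain = gains, offset = offsets))
  for (gi in seq_along(gains)) {
    for (oi in seq_along(offsets)) {
      tp <- pmin(pmax(patches * gains[gi] + offsets[oi], 0), 65535)
      probs <- predict_patches(model, tp)
      pred <- max.col(probs, ties.method = "first") - 1L
      cm <- confusion(labels, pred, n_levels)
      confusions[[sprintf("g%g_o%g", gains[gi], offsets[oi])]] <- cm
      within_one[gi, oi] <- within_k_accuracy(cm, 1L)
    }
  }
  structure(list(confusions = confusions, within_one = within_one,
                 gains = gains, offsets = offsets),
            class = "robustness_grid")
}
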