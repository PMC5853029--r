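test_that("threshold selection matches the exhaustive oracle", {
  withr::with_seed(77, {
    for (i in 1:50) {
      n <- sample(20:1000, 1)
      labels <- stats::rbinom(n, 1, stats::runif(1, 0.2, 0.8))
      if (length(unique(labels)) < 2) labels[1:2] <- c(0L, 1L)
      scores <- stats::rnorm(n) + 1.5 * labels
      sel <- select_threshold(scores, labels, validation_fraction = 1)
      expect_equal(sel$validation_f_score, oracle_best_f(scores, labels))
    }
  })
})

test_that("threshold selection handles toy and degenerate inputs", {
  sel <- select_threshold(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1),
                          validation_fraction = 1)
  expect_equal(sel$validation_f_score, 1)
  expect_gt(sel$threshold, 0.2)
  expect_lte(sel$threshold, 0.8)

  # separable scores: validation F-score 1 with threshold inside the gap
  sep <- select_threshold(c(1:5, 101:105), rep(c(0, 1), each = 5),
                          validation_fraction = 1)
  expect_equal(sep$validation_f_score, 1)
  expect_true(sep$threshold > 5 && sep$threshold <= 101)

  expect_error(select_threshold(1:10, rep(1, 10), validation_fraction = 1),
               "single class")
})

test_that("binary evaluation computes precision, recall and F-score", {
  perfect <- binary_evaluate(c(1, 2, 8, 9), c(0, 0, 1, 1), threshold = 5)
  expect_equal(perfect$f_score, 1)
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$recall, 1)

  # 4 true positives + 1 false positive, nothing missed:
  # precision 0.8, recall 1.0 -> F = 8/9
  res <- binary_evaluate(scores = c(9, 9, 9, 9, 9, 1),
                         labels = c(1, 1, 1, 1, 0, 0), threshold = 5)
  expect_equal(res$precision, 0.8)
  expect_equal(res$recall, 1)
  expect_equal(res$f_score, 8 / 9)

  none <- binary_evaluate(c(1, 2), c(1, 1), threshold = 10)
  expect_true(none$no_positive_calls)
  expect_equal(none$precision, 0)
  expect_error(binary_evaluate(numeric(0), integer(0), 1), "empty")
  expect_error(binary_evaluate(1:3, c(0, 1, 1), NA), "finite")
})

test_that("the 10%/90% split protocol evaluates only held-out images", {
  withr::with_seed(13, {
    scores <- c(stats::rnorm(100, 2), stats::rnorm(100, 6))
    labels <- rep(c(0, 1), each = 100)
  })
  sel <- select_threshold(scores, labels, validation_fraction = 0.1,
                          seed = 3)
  expect_length(sel$validation_idx, 20)
  res <- binary_evaluate(scores, labels, sel)
  expect_equal(res$n_test, 180)
  expect_equal(res$split_seed, 3)
  expect_gt(res$f_score, 0.9)
})

test_that("F-score is invariant under monotone score transforms", {
  withr::with_seed(41, {
    scores <- stats::rnorm(60)
    labels <- as.integer(scores + stats::rnorm(60, sd = 0.5) > 0)
  })
  if (length(unique(labels)) < 2) labels[1:2] <- c(0L, 1L)
  a <- binary_evaluate(scores, labels, threshold = 0.3)
  b <- binary_evaluate(exp(scores), labels, threshold = exp(0.3))
  expect_equal(a$f_score, b$f_score)
})

test_that("whole-image predictions reduce to rankable scalars", {
  one_hot_pred <- function(i) {
    p <- numeric(11); p[i + 1] <- 1
    structure(list(aggregate_distribution = p, aggregate_certainty = 1,
                   mean_certainty = 1, predicted_level = i, n_patches = 1),
              class = "whole_image_prediction")
  }
  expect_equal(model_binary_score(one_hot_pred(0)), 0)
  expect_equal(model_binary_score(one_hot_pred(10)), 10)
  uni <- one_hot_pred(0)
  uni$aggregate_distribution <- rep(1 / 11, 11)
  expect_equal(model_binary_score(uni), 5)
  expect_equal(model_binary_score(one_hot_pred(4), method = "argmax"), 4)
  expect_equal(model_binary_score(one_hot_pred(0), method = "p_out"), 0)
})

test_that("confusion matrices count pairs exactly", {
  perfect <- confusion(0:10, 0:10)
  expect_equal(perfect, diag(1L, 11), ignore_attr = TRUE)

  single <- confusion(3, 5)
  expect_equal(single[4, 6], 1L)
  expect_equal(sum(single), 1L)

  withr::with_seed(4, {
    t_ <- sample(0:10, 200, TRUE); p_ <- sample(0:10, 200, TRUE)
  })
  cm <- confusion(t_, p_)
  expect_equal(sum(cm), 200L)
  expect_equal(unname(rowSums(cm)), as.integer(table(factor(t_, 0:10))))
  expect_error(confusion(11, 0), "range")
})

test_that("within-k accuracy measures the diagonal band", {
  diag_cm <- diag(5L, 11)
  expect_equal(within_k_accuracy(diag_cm, 0), 1)
  off_one <- matrix(0L, 11, 11)
  off_one[cbind(1:10, 2:11)] <- 3L
  expect_equal(within_k_accuracy(off_one, 1), 1)
  expect_equal(within_k_accuracy(off_one, 0), 0)
  withr::with_seed(9, cm <- matrix(rpois(121, 3), 11, 11))
  expect_equal(within_k_accuracy(cm, 10), 1)
  accs <- vapply(0:10, within_k_accuracy, numeric(1), cm = cm)
  expect_true(all(diff(accs) >= 0))
  expect_error(within_k_accuracy(matrix(0, 11, 11)), "empty")
})

test_that("the robustness grid's identity cell equals plain evaluation", {
  model <- shared_model()
  test_set <- shared_dataset()$test
  grid <- robustness_grid(model, test_set, gains = 1, offsets = 0)
  keep <- which(test_set$foreground)
  probs <- predict_patches(model, test_set$patches[, , keep, drop = FALSE])
  cm <- confusion(test_set$labels[keep],
                  max.col(probs, ties.method = "first") - 1L, 11)
  expect_equal(grid$confusions[["g1_o0"]], cm)
  expect_equal(grid$within_one[1, 1], within_k_accuracy(cm, 1))
})
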