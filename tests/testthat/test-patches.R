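test_that("random patch extraction stays in bounds and is seeded", {
  img <- matrix(seq_len(84 * 84), 84, 84)
  expect_equal(unclass(extract_random_patch(img)),
               unclass(img), ignore_attr = TRUE)

  big <- matrix(0, 520, 696)
  for (s in 1:25) {
    p <- extract_random_patch(big, seed = s)
    expect_gte(attr(p, "row"), 0)
    expect_lte(attr(p, "row"), 520 - 84)
    expect_gte(attr(p, "col"), 0)
    expect_lte(attr(p, "col"), 696 - 84)
  }
  expect_identical(extract_random_patch(big, seed = 3),
                   extract_random_patch(big, seed = 3))
  expect_error(extract_random_patch(matrix(0, 50, 90)), "smaller")
})

test_that("tiling produces a disjoint full-coverage grid", {
  img <- matrix(stats::runif(520 * 696), 520, 696)
  tl <- tile_patches(img)
  expect_equal(tl$n_rows, 6) # floor(520 / 84)
  expect_equal(tl$n_cols, 8) # floor(696 / 84)
  expect_equal(dim(tl$patches)[3], 48)
  expect_false(any(duplicated(cbind(tl$row, tl$col))))
  # each tile is an exact crop (disjoint by grid construction)
  for (i in c(1, 17, 48)) {
    r0 <- tl$row[i] * 84 + 1; c0 <- tl$col[i] * 84 + 1
    expect_equal(tl$patches[, , i], img[r0:(r0 + 83), c0:(c0 + 83)])
  }
  one <- tile_patches(matrix(1, 84, 84))
  expect_equal(dim(one$patches)[3], 1)
  expect_equal(c(one$row, one$col), c(0L, 0L))
})

test_that("ranked probability score equals ordinal distance for hard calls", {
  n <- 11
  one_hot <- function(i) { p <- numeric(n); p[i + 1] <- 1; p }
  for (true in c(0, 3, 10)) {
    expect_equal(rps_loss(one_hot(true), true), 0)
    for (d in 1:3) {
      if (true + d < n) expect_equal(rps_loss(one_hot(true + d), true), d)
      if (true - d >= 0) expect_equal(rps_loss(one_hot(true - d), true), d)
    }
  }
  expect_equal(rps_loss(rep(1 / n, n), 0), 385 / 121)
  # strictly increasing in ordinal distance
  costs <- vapply(0:5, function(d) rps_loss(one_hot(d), 0), numeric(1))
  expect_true(all(diff(costs) > 0))
  expect_error(rps_loss(rep(0.2, 11), 0), "normalized")
  expect_error(rps_loss(one_hot(1), 11), "range")
})

test_that("training reduces the RPS loss and is reproducible", {
  model <- shared_model()
  tr <- model$loss_trace
  expect_lt(mean(utils::tail(tr, 25)), mean(utils::head(tr, 25)))
  expect_true(all(is.finite(tr)))

  cfg <- desk_train_config(steps = 12, batch_size = 8, seed = 21)
  m1 <- train_focus_model(shared_dataset()$train, cfg = cfg)
  m2 <- train_focus_model(shared_dataset()$train, cfg = cfg)
  expect_identical(m1$loss_trace, m2$loss_trace)
  expect_identical(m1$weights$W1, m2$weights$W1)
})

test_that("a missing class warns during training", {
  data <- shared_dataset()
  sub <- which(data$train$labels != 5)
  crippled <- labeled_patch_set(data$train$patches[, , sub],
                               data$train$labels[sub],
                               data$train$foreground[sub],
                               data$train$scene_id[sub], 11)
  expect_warning(
    train_focus_model(crippled,
                      cfg = desk_train_config(steps = 2, batch_size = 4)),
    "levels")
})

test_that("patch predictions are valid, deterministic distributions", {
  model <- shared_model()
  data <- shared_dataset()
  patch <- data$test$patches[, , 1]
  p1 <- predict_patch(model, patch)
  expect_length(p1, 11)
  expect_true(all(p1 >= 0))
  expect_equal(sum(p1), 1, tolerance = 1e-6)
  expect_identical(p1, predict_patch(model, patch))
  expect_error(predict_patch(model, matrix(0, 50, 50)), "84x84")

  probs <- predict_patches(model, data$test$patches)
  expect_equal(dim(probs), c(dim(data$test$patches)[3], 11))
  expect_equal(rowSums(probs), rep(1, nrow(probs)), tolerance = 1e-5)
})

test_that("the trained model separates extreme defocus levels", {
  model <- shared_model()
  data <- shared_dataset()
  fg <- data$test$foreground
  lv0 <- which(data$test$labels == 0 & fg)
  lv10 <- which(data$test$labels == 10 & fg)
  probs0 <- predict_patches(model, data$test$patches[, , lv0, drop = FALSE])
  probs10 <- predict_patches(model, data$test$patches[, , lv10, drop = FALSE])
  mean_level <- function(pr) mean(pr %*% 0:10)
  expect_lt(mean_level(probs0), mean_level(probs10))
})
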