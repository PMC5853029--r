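test_that("certainty maps entropy onto [0, 1] as expected", {
  expect_equal(certainty_of(rep(1 / 11, 11)), 0)
  one_hot <- c(1, rep(0, 10))
  expect_equal(certainty_of(one_hot), 1)
  expect_equal(certainty_of(c(0.5, 0.5, rep(0, 9))), 1 - log(2) / log(11))
  expect_error(certainty_of(rep(0.2, 11)), "normalized")
})

test_that("certainty is permutation invariant and decreasing in entropy", {
  withr::with_seed(8, {
    for (i in 1:20) {
      p <- random_distribution()
      expect_equal(certainty_of(p), certainty_of(sample(p)))
    }
  })
  # mixing any distribution toward uniform lowers certainty
  p <- c(0.6, 0.2, 0.1, 0.05, 0.05, rep(0, 6))
  mixes <- vapply(seq(0, 1, by = 0.2), function(a) {
    certainty_of((1 - a) * p + a / 11)
  }, numeric(1))
  expect_true(all(diff(mixes) < 0))
})

make_preds <- function(probs) {
  df <- as.data.frame(probs)
  names(df) <- paste0("p", 0:(ncol(probs) - 1))
  df$row <- seq_len(nrow(probs)) - 1L
  df$col <- integer(nrow(probs))
  df$predicted_level <- max.col(probs, ties.method = "first") - 1L
  df$certainty <- if (nrow(probs)) apply(probs, 1, certainty_of) else numeric(0)
  df
}

test_that("aggregation weights patches by certainty", {
  one_hot <- c(1, rep(0, 10))
  uniform <- rep(1 / 11, 11)

  single <- aggregate_image(make_preds(matrix(one_hot, 1)))
  expect_equal(single$aggregate_distribution, one_hot)
  expect_equal(single$aggregate_certainty, 1)
  expect_equal(single$mean_certainty, 1)

  pair <- aggregate_image(make_preds(rbind(one_hot, one_hot)))
  expect_equal(pair$aggregate_distribution, one_hot)

  # a zero-certainty (uniform) patch carries zero weight
  mixed <- aggregate_image(make_preds(rbind(one_hot, uniform)))
  expect_equal(mixed$aggregate_distribution, one_hot)
  expect_equal(mixed$mean_certainty, 0.5)

  expect_error(aggregate_image(make_preds(matrix(numeric(0), 0, 11))))
  expect_warning(
    flat <- aggregate_image(make_preds(rbind(uniform, uniform))),
    "zero")
  expect_equal(flat$aggregate_distribution, uniform)
})

test_that("aggregation is order invariant and yields valid distributions", {
  withr::with_seed(31, {
    for (i in 1:10) {
      probs <- t(replicate(6, random_distribution()))
      a <- aggregate_image(make_preds(probs))
      b <- aggregate_image(make_preds(probs[sample(6), ]))
      expect_equal(a$aggregate_distribution, b$aggregate_distribution)
      expect_true(all(a$aggregate_distribution >= 0))
      expect_equal(sum(a$aggregate_distribution), 1, tolerance = 1e-9)
      expect_equal(a$aggregate_certainty,
                   certainty_of(a$aggregate_distribution))
    }
  })
})

test_that("annotation draws level-hued, certainty-lit borders", {
  img <- matrix(1000, 84, 84)
  empty <- annotate_image(img, make_preds(matrix(numeric(0), 0, 11)))
  expect_equal(dim(empty), c(84, 84, 3))
  expect_equal(empty[, , 1], empty[, , 2]) # still grayscale

  pred <- make_preds(matrix(c(1, rep(0, 10)), 1))
  ann <- annotate_image(img, pred)
  # level 0, certainty 1 -> pure red border at full lightness
  expect_equal(as.vector(ann[1, 1, ]), c(1, 0, 0))
  # interior untouched (still gray)
  expect_equal(ann[42, 42, 1], ann[42, 42, 3])

  two <- make_preds(matrix(c(1, rep(0, 10)), 1))
  two$row <- 2L # grid row outside a 84x84 image
  expect_error(annotate_image(img, two), "outside")
})

test_that("certainty scatter reduces to the diagonal for uniform images", {
  one_hot <- c(1, rep(0, 10))
  p <- random_distribution()
  # images made of identical patches sit on the diagonal
  same <- aggregate_image(make_preds(rbind(p, p, p)))
  expect_equal(same$mean_certainty, same$aggregate_certainty,
               tolerance = 1e-9)
  tab <- certainty_scatter(list(same, aggregate_image(make_preds(matrix(one_hot, 1)))))
  expect_equal(nrow(tab), 2)
  expect_equal(tab$mean_certainty[2], tab$aggregate_certainty[2])
  expect_named(tab, c("mean_certainty", "aggregate_certainty",
                      "predicted_level"))
})

test_that("montage occupies one cell per (level, certainty bin) with samples", {
  one_hot <- c(1, rep(0, 10))
  patches <- array(500, c(84, 84, 3))
  preds <- make_preds(rbind(one_hot, one_hot, one_hot))
  m <- prediction_montage(patches, preds)
  expect_equal(sum(m$occupancy > 0), 1)
  # certainty 1.0 falls in the top (right-closed) bin
  expect_equal(m$occupancy[1, 10], 3)
  expect_equal(dim(m$montage), c(11 * 84, 10 * 84, 3))
  expect_equal(sum(m$occupancy), nrow(preds))
})
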