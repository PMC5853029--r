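test_that("radial PSD localizes pure tones and flags constants", {
  n <- 128
  f0 <- 16 / n # cycles per pixel, along rows
  img <- matrix(rep(cos(2 * pi * f0 * (0:(n - 1))), n), n, n)
  psd <- radial_psd(img, n_bins = 32)
  peak_bin <- which.max(psd$power)
  expect_lt(abs(psd$frequency[peak_bin] - f0), 0.5 / 32)
  expect_gt(psd$power[peak_bin], 0.99 * sum(psd$power))

  expect_true(radial_psd(matrix(5, 32, 32))$constant)
  expect_error(radial_psd(matrix(0, 8, 8)), "16x16")
})

test_that("radial PSD is isotropic (rotation invariant)", {
  withr::with_seed(2, img <- matrix(stats::rnorm(128 * 128), 128, 128))
  a <- radial_psd(img, n_bins = 32)
  b <- radial_psd(t(img)[, 128:1], n_bins = 32) # 90 degree rotation
  expect_equal(a$power, b$power, tolerance = 1e-9)
})

test_that("PLLS recovers prescribed spectral slopes", {
  # amplitude ~ f^-1 (power ~ f^-2) across the whole spectrum
  slopes2 <- vapply(1:3, function(s) plls(power_law_image(512, -2, s)),
                    numeric(1))
  expect_lt(max(abs(slopes2 - (-2))), 0.15)
  # white noise: flat spectrum
  flat <- vapply(4:8, function(s) {
    withr::with_seed(s, plls(matrix(stats::rnorm(512^2), 512, 512)))
  }, numeric(1))
  expect_lt(abs(mean(flat)), 0.1)
  expect_error(plls(matrix(1, 32, 32)), "constant")
})

test_that("PLLS is invariant to gain and offset but drops under defocus", {
  sh <- shared_stack()
  img <- sh$scene$image
  s0 <- plls(img)
  expect_equal(plls(img * 3.7 + 450), s0, tolerance = 1e-9)

  blurred <- defocus_image(img, compute_psf(optical_params(), 6))
  expect_lt(plls(blurred), s0)
})

test_that("PLLS orders defocus stacks (whole-image and patchwise)", {
  p <- optical_params()
  kernels <- shared_kernels()
  rho_w <- rho_p <- numeric(2)
  patch_means <- matrix(0, 2, 11)
  for (s in 1:2) {
    sc <- make_scene(scene_spec(), seed = s)
    st <- generate_defocus_stack(sc$image, p, sensor_model(),
                                 seed = 100 + s, kernels = kernels)
    sw <- vapply(st$images, plls, numeric(1))
    sp <- vapply(st$images, function(im) plls_patchwise(im)$score,
                 numeric(1))
    rho_w[s] <- stats::cor(0:10, sw, method = "spearman")
    rho_p[s] <- stats::cor(0:10, sp, method = "spearman")
    patch_means[s, ] <- sp
  }
  expect_true(all(rho_w <= -0.9))
  expect_true(all(rho_p <= -0.9))
  # patchwise score decreases with level on average over seeds
  expect_true(all(diff(colMeans(patch_means)) < 0))
})

test_that("patchwise PLLS reduces to the whole-image metric on one tile", {
  sh <- shared_stack()
  # crop a window that contains foreground (a constant patch has no PSD)
  ctr <- which(sh$scene$mask, arr.ind = TRUE)[1, ]
  r0 <- min(max(ctr[1] - 42, 1), nrow(sh$scene$image) - 83)
  c0 <- min(max(ctr[2] - 42, 1), ncol(sh$scene$image) - 83)
  one <- sh$scene$image[r0:(r0 + 83), c0:(c0 + 83)]
  pw <- plls_patchwise(one)
  expect_equal(pw$score, plls(one))
  expect_length(pw$slopes, 1)

  tiled <- rbind(cbind(one, one), cbind(one, one))
  pw4 <- plls_patchwise(tiled)
  expect_equal(pw4$score, plls(one), tolerance = 1e-9)
  expect_error(plls_patchwise(matrix(1, 168, 168)), "constant")
})
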