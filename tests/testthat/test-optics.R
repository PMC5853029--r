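test_that("optical parameter invariants are enforced", {
  p <- optical_params()
  expect_equal(p$k, 2 * pi / p$wavelength)
  expect_error(optical_params(numerical_aperture = 1.2), "refractive_index")
  expect_error(optical_params(wavelength = -1), "wavelength")
  expect_error(optical_params(n_levels = 1), "n_levels")
  expect_error(optical_params(numerical_aperture = NaN), "finite")
  expect_error(sensor_model(gain = 0), "gain")
  expect_error(sensor_model(offset = -1), "offset")
})

test_that("in-focus PSF matches the Airy closed form", {
  p <- optical_params()
  k0 <- compute_psf(p, z = 0, radius = 8)
  r_nm <- sqrt(outer((-8:8)^2, (-8:8)^2, "+")) * p$pixel_size * 1000
  v <- p$k * (p$numerical_aperture / p$refractive_index) * r_nm
  airy <- ifelse(v == 0, 1, (2 * besselJ(v, 1) / v)^2)
  airy <- airy / sum(airy)
  expect_lt(max(abs(airy - k0$weights)), 1e-3)
})

test_that("PSF kernels are normalized, non-negative, symmetric in z and r", {
  p <- optical_params()
  for (z in c(0, 4, 13.7, 20)) {
    k <- compute_psf(p, z)
    expect_true(all(k$weights >= 0))
    expect_lt(abs(sum(k$weights) - 1), 1e-9)
    # radial symmetry: invariant under transpose and flips
    expect_equal(k$weights, t(k$weights), tolerance = 1e-12)
    expect_equal(k$weights, k$weights[nrow(k$weights):1, ], tolerance = 1e-12)
  }
  expect_equal(compute_psf(p, 4)$weights, compute_psf(p, -4)$weights)
})

test_that("doubling the quadrature nodes leaves kernels unchanged", {
  p <- optical_params()
  a <- compute_psf(p, 20, radius = 28, n_nodes = 201)
  b <- compute_psf(p, 20, radius = 28, n_nodes = 401)
  expect_lt(max(abs(a$weights - b$weights)), 1e-6)
})

test_that("blur diameter spans ~3-30 px and grows linearly with |z|", {
  p <- optical_params()
  d <- vapply(1:10, function(L) energy_diameter(compute_psf(p, 2 * L)),
              numeric(1))
  expect_true(all(diff(d) > 0))
  d10 <- d[10] # level 10, z = 20 um
  expect_gte(d10, 20)
  expect_lte(d10, 40)
  fit <- stats::lm(d ~ seq_len(10))
  expect_lt(max(abs(stats::residuals(fit)) / abs(stats::fitted(fit))), 0.25)
})

test_that("a too-small kernel radius triggers a truncation warning", {
  p <- optical_params()
  expect_warning(compute_psf(p, 20, radius = 6), "truncat")
})

test_that("defocusing preserves constants, impulses and total intensity", {
  p <- optical_params()
  k <- compute_psf(p, 6)
  const <- matrix(37.5, 64, 64)
  expect_equal(defocus_image(const, k), const, tolerance = 1e-9)

  imp <- matrix(0, 61, 61); imp[31, 31] <- 1
  out <- defocus_image(imp, k)
  r <- (nrow(k$weights) - 1) / 2
  expect_equal(out[(31 - r):(31 + r), (31 - r):(31 + r)], k$weights,
               tolerance = 1e-9)

  # interior blob: total intensity conserved within 1%
  blob <- matrix(0, 200, 200)
  d2 <- outer((1:200 - 100)^2, (1:200 - 100)^2, "+")
  blob[d2 <= 16] <- 500
  blurred <- defocus_image(blob, compute_psf(p, 8))
  expect_lt(abs(sum(blurred) - sum(blob)) / sum(blob), 0.01)
  expect_error(defocus_image(matrix(1, 10, 10), compute_psf(p, 20)), "larger")
})

test_that("blob energy radius grows monotonically with defocus depth", {
  p <- optical_params()
  blob <- matrix(0, 180, 180)
  d2 <- outer((1:180 - 90)^2, (1:180 - 90)^2, "+")
  blob[d2 <= 25] <- 1000
  radius80 <- function(img) {
    d <- sqrt(outer((1:180 - 90)^2, (1:180 - 90)^2, "+"))
    o <- order(d)
    cum <- cumsum(img[o]) / sum(img)
    d[o][which(cum >= 0.8)[1]]
  }
  r80 <- vapply(seq(0, 20, by = 4), function(z) {
    radius80(if (z == 0) blob else defocus_image(blob, compute_psf(p, z)))
  }, numeric(1))
  expect_true(all(diff(r80) >= 0))
})

test_that("Poisson noise follows the sensor model", {
  sn <- sensor_model(offset = 100, gain = 2)
  flat_offset <- matrix(100, 50, 50)
  expect_equal(apply_poisson_noise(flat_offset, sn, seed = 1), flat_offset)

  uni <- matrix(5100, 320, 320) # 1.024e5 pixels
  noisy <- apply_poisson_noise(uni, sn, seed = 2)
  expected_var <- sn$gain * (5100 - sn$offset)
  expect_lt(abs(stats::var(as.vector(noisy)) / expected_var - 1), 0.05)

  expect_identical(apply_poisson_noise(uni, sn, seed = 7),
                   apply_poisson_noise(uni, sn, seed = 7))
  expect_error(apply_poisson_noise(matrix(-1, 2, 2), sn), "0, 65535")
})

test_that("defocus stacks enumerate the levels at the right depths", {
  sc <- make_scene(small_spec(), seed = 1)
  st <- generate_defocus_stack(sc$image, optical_params(), sensor_model(),
                               seed = 4)
  expect_identical(st$levels, 0:10)
  expect_equal(st$z, seq(0, 20, by = 2))
  expect_length(st$images, 11)
})

test_that("gain/offset augmentation is log-uniform within range", {
  img <- matrix(c(100, 4000), 20, 20)
  near_id <- augment_gain_offset(img, gain_range = c(1, 1),
                                 offset_range = c(1e-9, 1e-9), seed = 1)
  expect_equal(near_id, img, tolerance = 1e-6)

  # recover each drawn gain from a two-point image: g = diff(out)/diff(img)
  probe <- matrix(c(1000, 2000), 1, 2)
  draws <- vapply(seq_len(10000), function(s) {
    out <- augment_gain_offset(probe, seed = s)
    (out[1, 2] - out[1, 1]) / 1000
  }, numeric(1))
  expect_true(all(draws >= 0.2 - 1e-9 & draws <= 5 + 1e-9))
  expect_lt(abs(exp(mean(log(draws))) - 1), 0.03)

  out <- augment_gain_offset(matrix(60000, 4, 4), seed = 3)
  expect_true(all(out >= 0 & out <= 65535))
  expect_error(augment_gain_offset(img, gain_range = c(0, 2)), "positive")
})
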