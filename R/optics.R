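#' Optical parameters of the microscope forward model
#'
#' Bundles the constants of the scalar defocus model: numerical aperture,
#' immersion refractive index, emission wavelength, the z-spacing between
#' successive defocus levels, the camera pixel size and the number of ordered
#' defocus classes. The wavenumber `k = 2 * pi / wavelength` is derived and
#' stored alongside.
#'
#' @param numerical_aperture Objective NA (dimensionless), must satisfy
#'   `0 < NA < refractive_index`.
#' @param refractive_index Immersion medium refractive index (dimensionless).
#' @param wavelength Emission wavelength in nanometres.
#' @param z_step Axial spacing between defocus levels, in micrometres.
#' @param pixel_size Camera pixel size at the sample, in micrometres per
#'   pixel (e.g. a 6.5 um sensor pixel at 20x magnification with 2x binning
#'   gives 0.65 um/px).
#' @param n_levels Number of ordered defocus classes (level 0 = in focus).
#' @return An object of class `optical_params`.
#' @examples
#' optical_params()
#' @export
optical_params <- function(numerical_aperture = 0.5, refractive_index = 1.0,
                           wavelength = 500, z_step = 2, pixel_size = 0.65,
                           n_levels = 11L) {
  vals <- c(numerical_aperture, refractive_index, wavelength, z_step,
            pixel_size, n_levels)
  if (any(!is.finite(vals))) {
    stop("all optical parameters must be finite", call. = FALSE)
  }
  if (numerical_aperture <= 0 || numerical_aperture >= refractive_index) {
    stop("need 0 < numerical_aperture < refractive_index", call. = FALSE)
  }
  if (wavelength <= 0) stop("wavelength must be positive", call. = FALSE)
  if (z_step <= 0) stop("z_step must be positive", call. = FALSE)
  if (pixel_size <= 0) stop("pixel_size must be positive", call. = FALSE)
  if (n_levels < 2) stop("n_levels must be at least 2", call. = FALSE)
  structure(list(
    numerical_aperture = numerical_aperture,
    refractive_index = refractive_index,
    wavelength = wavelength,
    k = 2 * pi / wavelength,
    z_step = z_step,
    pixel_size = pixel_size,
    n_levels = as.integer(n_levels)
  ), class = "optical_params")
}

#' @export
print.optical_params <- function(x, ...) {
  cat(sprintf(
    "Optical parameters: NA=%.3g, n=%.3g, lambda=%.4g nm, z_step=%.3g um, pixel_size=%.3g um/px, %d levels\n",
    x$numerical_aperture, x$refractive_index, x$wavelength, x$z_step,
    x$pixel_size, x$n_levels))
  invisible(x)
}

#' Camera sensor model
#'
#' Digital offset (black level) and gain of the camera, used to convert
#' between digital counts and photoelectrons when simulating shot noise.
#'
#' @param offset Digital counts added by the camera (black level), `>= 0`.
#' @param gain Digital counts per photoelectron, `> 0`.
#' @return An object of class `sensor_model`.
#' @export
sensor_model <- function(offset = 50, gain = 2) {
  if (!is.finite(offset) || offset < 0) {
    stop("offset must be finite and >= 0", call. = FALSE)
  }
  if (!is.finite(gain) || gain <= 0) {
    stop("gain must be finite and > 0", call. = FALSE)
  }
  structure(list(offset = offset, gain = gain), class = "sensor_model")
}

default_psf_radius <- function(params, z) {
  # 1.5x the geometric blur radius z*NA/n (converted to pixels) plus margin
  geom_px <- abs(z) * params$numerical_aperture / params$refractive_index /
    params$pixel_size
  max(4L, as.integer(ceiling(1.5 * geom_px) + 4L))
}

#' Defocus point spread function
#'
#' Evaluates the scalar diffraction PSF of a circular-aperture objective at
#' axial defocus `z`,
#' \deqn{h(x, y, z) = \left| C \int_0^1 J_0\!\big(k \tfrac{NA}{n} r \rho\big)
#'   \exp\!\big(-\tfrac{1}{2} j k \rho^2 z (\tfrac{NA}{n})^2\big)
#'   \rho \, d\rho \right|^2,}
#' where \eqn{r = \sqrt{x^2 + y^2}} is the physical distance from the optical
#' axis, \eqn{J_0} the Bessel function of the first kind of order zero,
#' \eqn{k = 2\pi/\lambda} the wavenumber and \eqn{C} the constant that
#' normalizes the discrete kernel to unit sum. At `z = 0` the integral has the
#' closed form \eqn{J_1(v)/v}, i.e. the kernel is the Airy pattern
#' \eqn{(2 J_1(v)/v)^2} with \eqn{v = k (NA/n) r}.
#'
#' The integral is evaluated by composite Simpson quadrature over
#' \eqn{\rho \in [0, 1]} on a fixed grid of `n_nodes` points.
#'
#' @param params An [optical_params()] object.
#' @param z Defocus depth in micrometres (any sign; the kernel depends on
#'   `|z|` only).
#' @param radius Kernel half-width in pixels; side length is `2 * radius + 1`.
#'   Default: `ceiling(1.5 * z * NA / n / pixel_size) + 4`, at least 4.
#' @param n_nodes Number of Simpson quadrature nodes (odd, `>= 201`).
#' @return An object of class `psf_kernel` with fields `weights` (unit-sum
#'   square matrix of odd side), `z` and `params`.
#' @examples
#' k0 <- compute_psf(optical_params(), z = 0)
#' sum(k0$weights)
#' @export
compute_psf <- function(params, z, radius = NULL, n_nodes = 201L) {
  stopifnot(inherits(params, "optical_params"))
  if (!is.finite(z)) stop("z must be finite", call. = FALSE)
  if (is.null(radius)) radius <- default_psf_radius(params, z)
  radius <- as.integer(radius)
  if (radius < 1) stop("radius must be >= 1", call. = FALSE)
  if (n_nodes < 3 || n_nodes %% 2 == 0) {
    stop("n_nodes must be odd and >= 3", call. = FALSE)
  }

  side <- 2L * radius + 1L
  # physical radial distance of every pixel centre, in nm
  px <- seq(-radius, radius)
  r_px <- sqrt(outer(px^2, px^2, "+"))
  r_nm <- r_px * params$pixel_size * 1000
  z_nm <- z * 1000
  na_over_n <- params$numerical_aperture / params$refractive_index

  rho <- seq(0, 1, length.out = n_nodes)
  w <- simpson_weights(n_nodes)
  # defocus phase term, independent of r
  phase <- exp(-0.5i * params$k * rho^2 * z_nm * na_over_n^2)
  # evaluate on unique radii only
  ru <- unique(as.vector(r_nm))
  amp <- vapply(ru, function(r) {
    integrand <- besselJ(params$k * na_over_n * r * rho, 0) * phase * rho
    val <- sum(w * integrand)
    Re(val)^2 + Im(val)^2
  }, numeric(1))
  weights <- matrix(amp[match(as.vector(r_nm), ru)], side, side)

  total <- sum(weights)
  # unnormalized mass that a much larger kernel would carry, estimated from
  # the geometric-optics energy spread: warn when the window clips > 10%
  if (radius < default_psf_radius(params, z) && truncated_mass(
        params, z, radius, n_nodes) > 0.1) {
    warning("kernel radius truncates more than 10% of the PSF mass",
            call. = FALSE)
  }
  weights <- weights / total
  structure(list(weights = weights, z = z, params = params),
            class = "psf_kernel")
}

simpson_weights <- function(n_nodes) {
  h <- 1 / (n_nodes - 1)
  w <- rep(c(2, 4), length.out = n_nodes)
  w[1] <- 1
  w[n_nodes] <- 1
  w * h / 3
}

truncated_mass <- function(params, z, radius, n_nodes) {
  big <- compute_psf_raw(params, z, default_psf_radius(params, z), n_nodes)
  small_r <- radius
  side <- nrow(big)
  c0 <- (side + 1L) %/% 2L
  idx <- (c0 - small_r):(c0 + small_r)
  1 - sum(big[idx, idx]) / sum(big)
}

# unnormalized kernel, internal (no truncation check)
compute_psf_raw <- function(params, z, radius, n_nodes) {
  side <- 2L * radius + 1L
  px <- seq(-radius, radius)
  r_nm <- sqrt(outer(px^2, px^2, "+")) * params$pixel_size * 1000
  na_over_n <- params$numerical_aperture / params$refractive_index
  rho <- seq(0, 1, length.out = n_nodes)
  w <- simpson_weights(n_nodes)
  phase <- exp(-0.5i * params$k * rho^2 * z * 1000 * na_over_n^2)
  ru <- unique(as.vector(r_nm))
  amp <- vapply(ru, function(r) {
    val <- sum(w * besselJ(params$k * na_over_n * r * rho, 0) * phase * rho)
    Re(val)^2 + Im(val)^2
  }, numeric(1))
  matrix(amp[match(as.vector(r_nm), ru)], side, side)
}

#' @export
print.psf_kernel <- function(x, ...) {
  cat(sprintf("PSF kernel: %dx%d px, z = %.3g um\n",
              nrow(x$weights), ncol(x$weights), x$z))
  invisible(x)
}

#' Diameter enclosing a given fraction of kernel energy
#'
#' Smallest circle (diameter in pixels, centred on the kernel centre) whose
#' interior pixels carry at least `fraction` of the kernel's total weight.
#'
#' @param kernel A [compute_psf()] kernel or a plain weight matrix.
#' @param fraction Energy fraction, default 0.8.
#' @return Diameter in pixels.
#' @export
energy_diameter <- function(kernel, fraction = 0.8) {
  w <- if (inherits(kernel, "psf_kernel")) kernel$weights else kernel
  radius <- (nrow(w) - 1L) %/% 2L
  px <- seq(-radius, radius)
  r <- sqrt(outer(px^2, px^2, "+"))
  o <- order(r)
  cum <- cumsum(w[o]) / sum(w)
  2 * r[o][which(cum >= fraction)[1]]
}

#' Synthetically defocus an image
#'
#' Convolves an in-focus image with a defocus PSF kernel. The image is padded
#' reflectively by the kernel radius before the (FFT-based) convolution so
#' that image borders do not acquire the dark halo that would itself mimic
#' defocus; total intensity is conserved up to boundary effects because the
#' kernel has unit sum.
#'
#' @param image Numeric matrix of non-negative intensities.
#' @param kernel A [compute_psf()] kernel (or unit-sum odd-sided matrix).
#' @return Matrix of the same dimensions as `image`.
#' @export
defocus_image <- function(image, kernel) {
  w <- if (inherits(kernel, "psf_kernel")) kernel$weights else kernel
  if (!is.matrix(image) || any(image < 0)) {
    stop("image must be a matrix of non-negative values", call. = FALSE)
  }
  if (nrow(w) > nrow(image) || ncol(w) > ncol(image)) {
    stop("kernel is larger than the image", call. = FALSE)
  }
  r <- (nrow(w) - 1L) %/% 2L
  if (r == 0L) return(image * w[1, 1])
  padded <- pad_reflect(image, r)
  conv <- EBImage::filter2(padded, w, boundary = "circular")
  conv[(r + 1):(r + nrow(image)), (r + 1):(r + ncol(image))]
}

pad_reflect <- function(image, r) {
  n <- nrow(image); m <- ncol(image)
  if (r >= n || r >= m) stop("padding exceeds image size", call. = FALSE)
  ri <- c(rev(seq_len(r) + 1L), seq_len(n), n - seq_len(r))
  ci <- c(rev(seq_len(r) + 1L), seq_len(m), m - seq_len(r))
  image[ri, ci]
}

#' Apply Poisson shot noise under a sensor model
#'
#' Converts digital counts to expected photoelectrons using the sensor
#' offset and gain, draws a Poisson sample per pixel, and converts back:
#' `e = max(image - offset, 0) / gain`, output
#' `clip(Poisson(e) * gain + offset, 0, 65535)`.
#'
#' @param image Numeric matrix of counts in the 16-bit range.
#' @param sensor A [sensor_model()].
#' @param seed Optional integer; when given the draw is reproducible and the
#'   caller's RNG state is left untouched.
#' @return Matrix of noisy counts, same shape as `image`.
#' @export
apply_poisson_noise <- function(image, sensor, seed = NULL) {
  stopifnot(inherits(sensor, "sensor_model"))
  if (any(image < 0) || any(image > 65535)) {
    stop("image values must lie in [0, 65535]", call. = FALSE)
  }
  draw <- function() {
    e <- pmax(image - sensor$offset, 0) / sensor$gain
    s <- matrix(stats::rpois(length(e), as.vector(e)), nrow(image))
    pmin(pmax(s * sensor$gain + sensor$offset, 0), 65535)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Generate an ordered defocus stack from one in-focus image
#'
#' Produces `n_levels` images: level `L` is the input convolved with the PSF
#' at `z = L * z_step` and then passed through the sensor noise model; level 0
#' is the noised original. Levels are ordered least to most defocused.
#'
#' All levels are convolved in one pass: the image is padded reflectively by
#' the largest kernel radius, Fourier-transformed once, and multiplied by
#' each kernel's (precomputable) transform.
#'
#' @param in_focus Clean in-focus image (numeric matrix).
#' @param params An [optical_params()] object.
#' @param sensor A [sensor_model()].
#' @param seed Optional integer seed for the noise draws.
#' @param kernels Optional precomputed list of PSF kernels for levels
#'   `1 .. n_levels - 1` (reused across scenes to avoid recomputation).
#' @param plan Optional [stack_fft_plan()] (kernel transforms at this image
#'   size, reused across scenes).
#' @return A list of class `defocus_stack`: `images` (list of matrices),
#'   `levels` (integer vector `0:(n_levels-1)`), `z` (depths in um).
#' @export
generate_defocus_stack <- function(in_focus, params, sensor, seed = NULL,
                                   kernels = NULL, plan = NULL) {
  stopifnot(inherits(params, "optical_params"))
  n <- params$n_levels
  if (is.null(plan)) {
    if (is.null(kernels)) {
      kernels <- lapply(seq_len(n - 1L), function(L) {
        compute_psf(params, z = L * params$z_step)
      })
    }
    plan <- stack_fft_plan(kernels, nrow(in_focus), ncol(in_focus))
  }
  seeds <- if (is.null(seed)) vector("list", n) else seed + seq_len(n) - 1L
  images <- vector("list", n)
  images[[1]] <- apply_poisson_noise(pmin(in_focus, 65535), sensor,
                                     seed = seeds[[1]])
  R <- plan$radius
  padded <- pad_reflect(in_focus, R)
  f <- stats::fft(padded)
  npx <- length(padded)
  for (L in seq_len(n - 1L)) {
    conv <- Re(stats::fft(f * plan$kernel_fft[[L]], inverse = TRUE)) / npx
    blurred <- conv[(R + 1):(R + nrow(in_focus)),
                    (R + 1):(R + ncol(in_focus))]
    blurred <- pmax(blurred, 0) # clip FFT ringing at the noise model's floor
    images[[L + 1L]] <- apply_poisson_noise(pmin(blurred, 65535), sensor,
                                            seed = seeds[[L + 1L]])
  }
  structure(list(images = images, levels = 0:(n - 1L),
                 z = (0:(n - 1L)) * params$z_step),
            class = "defocus_stack")
}

#' Precompute kernel transforms for fast stack generation
#'
#' Builds the padded-size Fourier transforms of a set of PSF kernels so
#' that [generate_defocus_stack()] can convolve every level of every scene
#' of a dataset with a single forward transform per scene.
#'
#' @param kernels List of [compute_psf()] kernels (levels `1..n_levels-1`).
#' @param height,width Image dimensions the plan is for.
#' @return An object of class `stack_fft_plan`.
#' @export
stack_fft_plan <- function(kernels, height, width) {
  radii <- vapply(kernels, function(k) (nrow(k$weights) - 1L) %/% 2L,
                  integer(1))
  R <- max(radii)
  hp <- height + 2L * R
  wp <- width + 2L * R
  kernel_fft <- lapply(kernels, function(k) {
    side <- nrow(k$weights)
    r <- (side - 1L) %/% 2L
    m <- matrix(0, hp, wp)
    m[seq_len(side), seq_len(side)] <- k$weights
    # circularly shift so the kernel centre sits at index (1, 1)
    ri <- c((r + 1L):hp, seq_len(r))
    ci <- c((r + 1L):wp, seq_len(r))
    stats::fft(m[ri, ci])
  })
  structure(list(kernel_fft = kernel_fft, radius = R, height = height,
                 width = width), class = "stack_fft_plan")
}

#' Random photometric gain/offset augmentation
#'
#' Draws a gain `g` log-uniformly from `gain_range` and an offset `o`
#' log-uniformly from `offset_range` and returns
#' `clip(image * g + o, 0, 65535)`. This is the augmentation that teaches the
#' patch classifier invariance to the wide range of foreground and background
#' intensities met across 16-bit microscope images.
#'
#' @param image Numeric matrix of counts.
#' @param gain_range Length-2 positive vector, low < high; default (0.2, 5).
#' @param offset_range Length-2 positive vector, low < high; default (1, 1000).
#' @param seed Optional integer seed.
#' @return Augmented image matrix.
#' @export
augment_gain_offset <- function(image, gain_range = c(0.2, 5),
                                offset_range = c(1, 1000), seed = NULL) {
  check_logu_range(gain_range, "gain_range")
  check_logu_range(offset_range, "offset_range")
  draw <- function() {
    g <- exp(stats::runif(1, log(gain_range[1]), log(gain_range[2])))
    o <- exp(stats::runif(1, log(offset_range[1]), log(offset_range[2])))
    pmin(pmax(image * g + o, 0), 65535)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

check_logu_range <- function(r, name) {
  if (length(r) != 2 || any(!is.finite(r)) || any(r <= 0) || r[1] > r[2]) {
    stop(sprintf("%s must be two positive finite values, low <= high (log-uniform sampling)",
                 name), call. = FALSE)
  }
  invisible(r)
}
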