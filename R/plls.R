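utils::globalVariables(c("mean_certainty", "aggregate_certainty",
                         "predicted_level"))

#' Radially averaged power spectral density
#'
#' Subtracts the image mean, computes the 2-D periodogram `|FFT|^2`, and
#' averages the spectral power within radial spatial-frequency bins. The DC
#' component is excluded; frequencies are in cycles per pixel, up to the
#' Nyquist limit 0.5.
#'
#' @param image Numeric matrix, at least 16 x 16.
#' @param n_bins Number of radial bins (default: half the smaller image
#'   dimension, capped at 128).
#' @param window Apply a Hann window before the FFT? Default `FALSE`
#'   (plain periodogram).
#' @return An object of class `radial_psd`: `frequency` (bin centres,
#'   ascending, in `(0, 0.5]`), `power` (mean power per bin), `constant`
#'   (flag: the image had no variance).
#' @export
radial_psd <- function(image, n_bins = NULL, window = FALSE) {
  stopifnot(is.matrix(image))
  if (nrow(image) < 16 || ncol(image) < 16) {
    stop("image must be at least 16x16", call. = FALSE)
  }
  if (is.null(n_bins)) n_bins <- min(min(dim(image)) %/% 2L, 128L)
  x <- image - mean(image)
  constant <- all(x == 0)
  if (window) {
    hr <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nrow(x)) - 1) / (nrow(x) - 1))
    hc <- 0.5 - 0.5 * cos(2 * pi * (seq_len(ncol(x)) - 1) / (ncol(x) - 1))
    x <- x * outer(hr, hc)
  }
  p <- Mod(stats::fft(x))^2
  fr <- fft_freq(nrow(x))
  fc <- fft_freq(ncol(x))
  f <- sqrt(outer(fr^2, fc^2, "+"))
  keep <- f > 0 & f <= 0.5
  edges <- seq(0, 0.5, length.out = n_bins + 1L)
  bin <- cut(f[keep], edges, labels = FALSE, include.lowest = FALSE)
  power <- vapply(seq_len(n_bins),
                  function(b) mean(p[keep][bin == b]), numeric(1))
  centre <- (edges[-1] + edges[-(n_bins + 1L)]) / 2
  ok <- !is.nan(power)
  structure(list(frequency = centre[ok], power = power[ok],
                 constant = constant),
            class = "radial_psd")
}

fft_freq <- function(n) {
  k <- seq_len(n) - 1L
  ifelse(k <= n %/% 2, k, k - n) / n
}

#' Power log-log slope (PLLS) focus metric
#'
#' Ordinary least-squares slope of `log(power)` against `log(frequency)`
#' over a fixed radial-frequency band. Defocus blur removes high spatial
#' frequencies, so blurrier images have a more negative slope; for natural
#' microscope images the value is negative. The metric is invariant to
#' multiplicative gain (which shifts only the intercept) and to additive
#' offset (the mean is removed before the FFT).
#'
#' The default fit band `[0.01, 0.05]` cycles/pixel is chosen to sit below
#' the first zero of the optical transfer function at the largest defocus
#' the classifier grades (a blur diameter near 30 pixels puts that zero at
#' about `3.83 / (pi * 30) = 0.04` cycles/pixel): above it the spectrum of a
#' strongly defocused image is dominated by the flat shot-noise floor, and a
#' slope fitted there saturates — or even rises — instead of tracking
#' defocus.
#'
#' @param image Numeric matrix.
#' @param fit_band Length-2 vector: frequency band (cycles/pixel) used for
#'   the line fit.
#' @param n_bins,window Passed to [radial_psd()].
#' @return Scalar slope.
#' @export
plls <- function(image, fit_band = c(0.01, 0.05), n_bins = NULL,
                 window = FALSE) {
  psd <- radial_psd(image, n_bins = n_bins, window = window)
  if (psd$constant) stop("PLLS is undefined for a constant image",
                         call. = FALSE)
  sel <- psd$frequency >= fit_band[1] & psd$frequency <= fit_band[2] &
    psd$power > 0
  if (sum(sel) < 3) stop("fewer than 3 usable frequency bins in fit band",
                         call. = FALSE)
  stats::coef(stats::lm(log(psd$power[sel]) ~ log(psd$frequency[sel])))[[2]]
}

#' PLLS within the patch framework
#'
#' Computes the PLLS slope on every non-overlapping tile of the image and
#' summarizes the image as the arithmetic mean of the finite patch slopes
#' (certainty weighting is undefined for a scalar metric).
#'
#' @param image Numeric matrix, at least `patch_size` in both dimensions.
#' @param patch_size Tile side (default 84).
#' @param fit_band,n_bins,window Passed to [plls()].
#' @return List with `slopes` (per patch, `NA` for constant patches), `row`,
#'   `col` (grid coordinates) and `score` (mean finite slope).
#' @export
plls_patchwise <- function(image, patch_size = 84, fit_band = c(0.01, 0.05),
                           n_bins = NULL, window = FALSE) {
  tiles <- tile_patches(image, patch_size)
  slopes <- vapply(seq_len(dim(tiles$patches)[3]), function(i) {
    tryCatch(plls(tiles$patches[, , i], fit_band = fit_band,
                  n_bins = n_bins, window = window),
             error = function(e) NA_real_)
  }, numeric(1))
  if (all(is.na(slopes))) {
    stop("PLLS is undefined on every patch (all constant)", call. = FALSE)
  }
  list(slopes = slopes, row = tiles$row, col = tiles$col,
       score = mean(slopes, na.rm = TRUE))
}
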