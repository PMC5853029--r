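#' Entropy-based prediction certainty
#'
#' Maps a class distribution to `1 - H(p) / log(N)` where
#' `H(p) = -sum(p * log(p))` is the Shannon entropy and `N` the number of
#' classes: 0 for a uniform (uninformative) distribution, 1 for a one-hot
#' (fully confident) one. `0 * log(0)` is taken as 0. Certainty measures only
#' the peakedness of the distribution — it is invariant to permutations of
#' `p` and carries no ordinal information.
#'
#' @param dist Numeric probability vector (sums to 1 within 1e-6).
#' @return Scalar in `[0, 1]`.
#' @examples
#' certainty_of(rep(1, 11) / 11)        # 0
#' certainty_of(c(1, rep(0, 10)))       # 1
#' @export
certainty_of <- function(dist) {
  if (abs(sum(dist) - 1) > 1e-6 || any(dist < -1e-12)) {
    stop("dist must be a normalized probability vector", call. = FALSE)
  }
  p <- dist[dist > 0]
  h <- -sum(p * log(p))
  max(0, min(1, 1 - h / log(length(dist))))
}

#' Certainty-weighted whole-image aggregation
#'
#' Combines per-patch class distributions into one whole-image distribution:
#' the certainty-weighted average `sum(c_k * p_k) / sum(c_k)`. The aggregate
#' certainty is the (normalized, entropy-based) certainty of that aggregate
#' distribution; the mean certainty is the arithmetic mean of the patch
#' certainties. Patches with certainty 0 (uniform output, typically empty
#' background) therefore carry no weight. If every patch has certainty 0 the
#' unweighted mean is used with a warning.
#'
#' @param patch_preds A `data.frame` from [predict_image_patches()] (columns
#'   `p0..p<N-1>`, `certainty`).
#' @return An object of class `whole_image_prediction` with
#'   `aggregate_distribution`, `aggregate_certainty`, `mean_certainty`,
#'   `predicted_level`, `n_patches`.
#' @export
aggregate_image <- function(patch_preds) {
  probs <- prob_matrix(patch_preds)
  if (nrow(probs) == 0) stop("no patch predictions to aggregate", call. = FALSE)
  cert <- patch_preds$certainty
  if (is.null(cert)) cert <- apply(probs, 1, certainty_of)
  w <- cert
  if (sum(w) <= 0) {
    warning("all patch certainties are zero; falling back to unweighted mean",
            call. = FALSE)
    w <- rep(1, nrow(probs))
  }
  agg <- as.vector(crossprod(probs, w)) / sum(w)
  agg <- agg / sum(agg)
  structure(list(
    aggregate_distribution = agg,
    aggregate_certainty = certainty_of(agg),
    mean_certainty = mean(cert),
    predicted_level = which.max(agg) - 1L,
    n_patches = nrow(probs)
  ), class = "whole_image_prediction")
}

#' @export
print.whole_image_prediction <- function(x, ...) {
  cat(sprintf(
    "Whole-image prediction: level %d (aggregate certainty %.2f, mean certainty %.2f, %d patches)\n",
    x$predicted_level, x$aggregate_certainty, x$mean_certainty, x$n_patches))
  invisible(x)
}

#' Hue palette for the defocus levels
#'
#' Eleven (or `n_levels`) evenly spaced hues with level 0 anchored at red
#' (best focus), at a given lightness/value.
#'
#' @param n_levels Number of levels.
#' @param value Brightness in `[0, 1]` (lightness encodes certainty).
#' @return Vector of hex colors.
#' @export
level_palette <- function(n_levels = 11L, value = 1) {
  grDevices::hsv(h = (seq_len(n_levels) - 1) / n_levels, s = 1, v = value)
}

#' Annotate an image with patch-level predictions
#'
#' Renders the grayscale image to RGB and draws a border around every
#' predicted patch; the border hue encodes the predicted defocus level
#' (level 0 = red) and its lightness increases linearly with certainty.
#'
#' @param image Numeric matrix of raw counts.
#' @param patch_preds `data.frame` from [predict_image_patches()].
#' @param patch_size Patch side in pixels.
#' @param border Border thickness in pixels.
#' @param display_gamma Gamma applied to the grayscale rendering (viewing
#'   aid only).
#' @return Numeric array `nrow x ncol x 3` with values in `[0, 1]`.
#' @export
annotate_image <- function(image, patch_preds, patch_size = 84, border = 3,
                           display_gamma = 0.45) {
  stopifnot(is.matrix(image))
  gray <- (image / max(image, 1))^display_gamma
  rgb <- array(rep(gray, 3), c(nrow(image), ncol(image), 3))
  if (nrow(patch_preds) == 0) return(rgb)
  n_levels <- ncol(prob_matrix(patch_preds))
  for (i in seq_len(nrow(patch_preds))) {
    r0 <- patch_preds$row[i] * patch_size + 1L
    c0 <- patch_preds$col[i] * patch_size + 1L
    r1 <- r0 + patch_size - 1L; c1 <- c0 + patch_size - 1L
    if (r1 > nrow(image) || c1 > ncol(image)) {
      stop("patch grid position outside the image", call. = FALSE)
    }
    col <- grDevices::col2rgb(level_palette(
      n_levels, value = patch_preds$certainty[i]
    )[patch_preds$predicted_level[i] + 1L]) / 255
    rows <- c(r0:(r0 + border - 1L), (r1 - border + 1L):r1)
    cols <- c(c0:(c0 + border - 1L), (c1 - border + 1L):c1)
    for (ch in 1:3) {
      rgb[rows, c0:c1, ch] <- col[ch]
      rgb[r0:r1, cols, ch] <- col[ch]
    }
  }
  rgb
}

#' Mean-versus-aggregate certainty table
#'
#' One row per image with its mean patch certainty, aggregate certainty and
#' aggregate predicted level — the coordinates of the certainty scatter plot
#' that separates consistent in-focus images, images with conflicting patch
#' calls, sparse images, and empty images.
#'
#' @param preds List of [aggregate_image()] results.
#' @return `data.frame` with columns `mean_certainty`, `aggregate_certainty`,
#'   `predicted_level`.
#' @export
certainty_scatter <- function(preds) {
  if (inherits(preds, "whole_image_prediction")) preds <- list(preds)
  stopifnot(length(preds) >= 1)
  data.frame(
    mean_certainty = vapply(preds, `[[`, numeric(1), "mean_certainty"),
    aggregate_certainty = vapply(preds, `[[`, numeric(1),
                                 "aggregate_certainty"),
    predicted_level = vapply(preds, `[[`, integer(1), "predicted_level")
  )
}

#' Plot the certainty scatter
#'
#' @param tab Table from [certainty_scatter()].
#' @param n_levels Number of defocus levels (for the hue palette).
#' @return A ggplot object.
#' @export
plot_certainty_scatter <- function(tab, n_levels = 11L) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  ggplot2::ggplot(tab, ggplot2::aes(
    x = mean_certainty, y = aggregate_certainty,
    colour = factor(predicted_level, levels = 0:(n_levels - 1L)))) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::scale_colour_manual(
      values = level_palette(n_levels), drop = FALSE,
      name = "predicted level") +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "mean certainty", y = "aggregate certainty")
}

#' Level-by-certainty prediction montage
#'
#' Builds an `n_levels x n_certainty_bins` montage: each cell shows one
#' sample patch whose predicted level and certainty fall in that cell,
#' rendered with its border annotation; combinations with no predictions
#' stay blank. Certainty bins partition `[0, 1]` left-open with a
#' right-closed last bin, so certainty 1.0 falls in the top bin.
#'
#' @param patches Array `84 x 84 x n` of the predicted patches.
#' @param patch_preds `data.frame` of their predictions (same order).
#' @param n_certainty_bins Number of certainty bins (default 10).
#' @return List with `montage` (RGB array, levels as rows, certainty
#'   increasing along columns) and `occupancy` (`n_levels x bins` count
#'   matrix of available predictions per cell).
#' @export
prediction_montage <- function(patches, patch_preds, n_certainty_bins = 10L) {
  stopifnot(length(dim(patches)) == 3,
            dim(patches)[3] == nrow(patch_preds), nrow(patch_preds) >= 1)
  ps <- dim(patches)[1]
  n_levels <- ncol(prob_matrix(patch_preds))
  bin <- pmin(pmax(ceiling(patch_preds$certainty * n_certainty_bins), 1L),
              n_certainty_bins)
  occupancy <- matrix(0L, n_levels, n_certainty_bins,
                      dimnames = list(level = 0:(n_levels - 1L),
                                      certainty_bin = seq_len(n_certainty_bins)))
  montage <- array(0, c(n_levels * ps, n_certainty_bins * ps, 3))
  for (L in seq_len(n_levels) - 1L) {
    for (b in seq_len(n_certainty_bins)) {
      hit <- which(patch_preds$predicted_level == L & bin == b)
      occupancy[L + 1L, b] <- length(hit)
      if (length(hit) == 0) next
      i <- hit[1]
      one <- patch_preds[i, , drop = FALSE]
      one$row <- 0L; one$col <- 0L
      cell <- annotate_image(patches[, , i], one, patch_size = ps)
      montage[(L * ps + 1):((L + 1) * ps),
              ((b - 1) * ps + 1):(b * ps), ] <- cell
    }
  }
  list(montage = montage, occupancy = occupancy)
}
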