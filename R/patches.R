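#' Extract one uniformly random patch
#'
#' Crops an exact `patch_size x patch_size` window at a uniformly random
#' top-left corner. The crop position is attached as attributes `row` and
#' `col` (0-based, row-major, anchored top-left).
#'
#' @param image Numeric matrix, at least `patch_size` in both dimensions.
#' @param patch_size Side of the square crop (default 84).
#' @param seed Optional integer seed; same seed, same crop.
#' @return The cropped matrix with attributes `row`, `col`.
#' @export
extract_random_patch <- function(image, patch_size = 84, seed = NULL) {
  check_patchable(image, patch_size)
  draw <- function() {
    r0 <- sample.int(nrow(image) - patch_size + 1L, 1L)
    c0 <- sample.int(ncol(image) - patch_size + 1L, 1L)
    out <- image[r0:(r0 + patch_size - 1L), c0:(c0 + patch_size - 1L)]
    attr(out, "row") <- r0 - 1L
    attr(out, "col") <- c0 - 1L
    out
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Tile an image into non-overlapping patches
#'
#' Cuts a regular grid of `patch_size x patch_size` tiles anchored at the
#' top-left corner; remainder rows/columns that do not fill a whole tile are
#' dropped. Grid coordinates are 0-based.
#'
#' @param image Numeric matrix.
#' @param patch_size Tile side (default 84).
#' @return List with `patches` (array `patch_size x patch_size x n`), `row`
#'   and `col` (integer grid coordinates per patch), `n_rows`, `n_cols`.
#' @export
tile_patches <- function(image, patch_size = 84) {
  check_patchable(image, patch_size)
  n_rows <- nrow(image) %/% patch_size
  n_cols <- ncol(image) %/% patch_size
  n <- n_rows * n_cols
  patches <- array(0, c(patch_size, patch_size, n))
  row <- integer(n); col <- integer(n)
  i <- 0L
  for (gc in seq_len(n_cols) - 1L) {
    for (gr in seq_len(n_rows) - 1L) {
      i <- i + 1L
      patches[, , i] <- image[(gr * patch_size + 1L):((gr + 1L) * patch_size),
                              (gc * patch_size + 1L):((gc + 1L) * patch_size)]
      row[i] <- gr; col[i] <- gc
    }
  }
  list(patches = patches, row = row, col = col,
       n_rows = n_rows, n_cols = n_cols)
}

check_patchable <- function(image, patch_size) {
  if (!is.matrix(image)) stop("image must be a matrix", call. = FALSE)
  if (nrow(image) < patch_size || ncol(image) < patch_size) {
    stop(sprintf("image (%dx%d) smaller than patch size %d",
                 nrow(image), ncol(image), patch_size), call. = FALSE)
  }
  invisible(image)
}
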