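#' Read a 16-bit grayscale image
#'
#' Reads a single-channel TIFF or PNG into an `image_record` holding raw
#' integer counts in `[0, 65535]`. 8-bit input is promoted to 16-bit by
#' multiplying by 257 (so 255 maps to 65535), with a message. Multi-channel
#' images are rejected: convert to grayscale upstream or pass
#' `channel` to select one.
#'
#' @param path File path ending in `.tif`, `.tiff` or `.png`.
#' @param channel Optional channel index to extract from a multi-channel
#'   file.
#' @param metadata Optional named list (scene/site id, z-index, channel
#'   name) carried along with the pixels.
#' @return An object of class `image_record`: `pixels` (matrix of counts),
#'   `path`, `metadata`.
#' @export
read_image <- function(path, channel = NULL, metadata = list()) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    arr <- tiff::readTIFF(path, as.is = TRUE, info = TRUE)
    bits <- attr(arr, "bits.per.sample") %||% 16L
    px <- arr
  } else if (ext == "png") {
    arr <- png::readPNG(path, info = TRUE) # scaled to [0, 1]
    info <- attr(arr, "info")
    bits <- if (!is.null(info$bit.depth)) info$bit.depth else 16L
    px <- arr * (2^bits - 1)
  } else {
    stop("unsupported image format: ", ext, " (use TIFF or PNG)",
         call. = FALSE)
  }
  if (length(dim(px)) == 3) {
    if (is.null(channel)) {
      stop("multi-channel image; pass `channel` to select one plane",
           call. = FALSE)
    }
    px <- px[, , channel]
  }
  px <- round(px)
  if (bits == 8L) {
    message("8-bit input promoted to 16-bit (values x 257)")
    px <- px * 257
  }
  image_record(px, path = path, metadata = metadata)
}

#' Construct an image record
#'
#' @param pixels Numeric matrix of counts in `[0, 65535]`.
#' @param path Source path (or `NA`).
#' @param metadata Named list of carried metadata.
#' @return An `image_record`.
#' @export
image_record <- function(pixels, path = NA_character_, metadata = list()) {
  stopifnot(is.matrix(pixels))
  if (any(pixels < 0) || any(pixels > 65535)) {
    stop("pixel values must lie in [0, 65535]", call. = FALSE)
  }
  structure(list(pixels = pixels, path = path, metadata = metadata),
            class = "image_record")
}

#' Write a grayscale image
#'
#' TIFF output is lossless 16-bit and is the round-trip format used
#' throughout; PNG output is 8-bit (the installed PNG writer has no 16-bit
#' mode) and is offered for quick viewing only — a warning marks the
#' precision loss.
#'
#' @param image An `image_record` or a plain numeric matrix of counts.
#' @param path Destination path (`.tif`/`.tiff` or `.png`).
#' @return The path, invisibly.
#' @export
write_image <- function(image, path) {
  px <- if (inherits(image, "image_record")) image$pixels else image
  stopifnot(is.matrix(px))
  px <- pmin(pmax(round(px), 0), 65535)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(px / 65535, path, bits.per.sample = 16L)
  } else if (ext == "png") {
    warning("PNG output is 8-bit; use TIFF for lossless 16-bit data",
            call. = FALSE)
    png::writePNG(px / 65535, path)
  } else {
    stop("unsupported image format: ", ext, call. = FALSE)
  }
  invisible(path)
}

#' Export a PSF kernel as a float TIFF for inspection
#'
#' @param kernel A [compute_psf()] kernel.
#' @param path Destination `.tif` path.
#' @return The path, invisibly.
#' @export
write_kernel <- function(kernel, path) {
  w <- if (inherits(kernel, "psf_kernel")) kernel$weights else kernel
  tiff::writeTIFF(w / max(w), path, bits.per.sample = 32L)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Remove a constant sensor artifact
#'
#' Subtracts a constant from every pixel and clips at zero — the
#' preprocessing used to strip a defective-sensor pedestal before
#' prediction.
#'
#' @param image Numeric matrix (or `image_record`).
#' @param constant Counts to subtract (default 1000).
#' @return Same type as the input.
#' @export
remove_artifact <- function(image, constant = 1000) {
  if (inherits(image, "image_record")) {
    image$pixels <- pmax(image$pixels - constant, 0)
    return(image)
  }
  pmax(image - constant, 0)
}

#' Select the best-focus image of a focal stack
#'
#' Returns the stack member with the largest standard deviation across all
#' pixels — the sharpest image of a sparse bright scene. Ties go to the
#' lowest z-index (list position).
#'
#' @param stack Non-empty list of `image_record`s or matrices.
#' @return The selected element, with attribute `z_index` (1-based
#'   position).
#' @export
select_best_focus <- function(stack) {
  if (length(stack) == 0) stop("empty focal stack", call. = FALSE)
  sds <- vapply(stack, function(im) {
    px <- if (inherits(im, "image_record")) im$pixels else im
    stats::sd(as.vector(px))
  }, numeric(1))
  i <- which.max(sds) # first maximum = lowest z-index on ties
  out <- stack[[i]]
  attr(out, "z_index") <- i
  out
}
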