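#' Specification of a synthetic nuclei-like scene
#'
#' Describes a sparse field of bright isotropic blobs on a constant dark
#' background, emulating a Hoechst-stained nuclei image: most of the frame
#' is background and foreground objects are compact and bright. Each blob
#' is a flat-top disk with a soft error-function edge of width
#' `blob_edge_width` pixels. The sharp boundary matters: it gives the
#' in-focus scene broadband spatial-frequency content (like real nuclei
#' edges) that defocus blur then removes — the signal every focus metric in
#' this package relies on. A purely Gaussian intensity profile would be
#' band-limited and leave nothing for defocus to remove.
#'
#' @param height,width Scene dimensions in pixels (default 520 x 696).
#' @param blob_count_range Integer range for the number of blobs per scene.
#' @param blob_radius_range Range for the blob (nucleus) radius, in pixels.
#' @param blob_peak_range Range for each blob's interior amplitude, counts.
#' @param background_offset Constant background level, in counts.
#' @param foreground_fraction_target Intended fraction of pixels covered by
#'   blob support (approximate; actual coverage depends on overlap).
#' @param blob_edge_width Gaussian width of the blob edge, in pixels.
#' @param patch_size Patch size the scene must accommodate (dimensions must
#'   be at least twice this).
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(height = 520, width = 696,
                       blob_count_range = c(80, 160),
                       blob_radius_range = c(4, 9),
                       blob_peak_range = c(3000, 12000),
                       background_offset = 100,
                       foreground_fraction_target = 0.04,
                       blob_edge_width = 0.8,
                       patch_size = 84) {
  stopifnot(height >= 2 * patch_size, width >= 2 * patch_size,
            all(blob_count_range >= 0), all(blob_radius_range > 0),
            all(blob_peak_range > 0), background_offset >= 0,
            foreground_fraction_target >= 0,
            foreground_fraction_target <= 1, blob_edge_width > 0)
  structure(list(
    height = as.integer(height), width = as.integer(width),
    blob_count_range = blob_count_range,
    blob_radius_range = blob_radius_range,
    blob_peak_range = blob_peak_range,
    background_offset = background_offset,
    foreground_fraction_target = foreground_fraction_target,
    blob_edge_width = blob_edge_width,
    patch_size = as.integer(patch_size)
  ), class = "scene_spec")
}

#' Generate one synthetic in-focus scene
#'
#' Draws blob count, positions, radii and peaks from the ranges in `spec`,
#' renders each blob as a flat-top disk with a soft error-function edge
#' added to the constant background, and returns both the image and the
#' binary mask of blob support (pixels inside the blob boundary).
#'
#' @param spec A [scene_spec()].
#' @param seed Optional integer; same seed, same scene.
#' @return List with `image` (matrix of counts) and `mask` (logical matrix).
#' @export
make_scene <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "scene_spec"))
  build <- function() {
    img <- matrix(spec$background_offset, spec$height, spec$width)
    mask <- matrix(FALSE, spec$height, spec$width)
    n_blobs <- sample_int_range(spec$blob_count_range)
    if (n_blobs == 0) return(list(image = img, mask = mask))
    # estimated coverage at the target: warn when the ranges cannot reach it
    mean_r <- mean(spec$blob_radius_range)
    est <- max(spec$blob_count_range) * pi * mean_r^2 /
      (spec$height * spec$width)
    if (est < spec$foreground_fraction_target / 2) {
      warning("blob ranges cannot reach foreground_fraction_target; best effort",
              call. = FALSE)
    }
    w <- spec$blob_edge_width
    for (b in seq_len(n_blobs)) {
      radius <- stats::runif(1, spec$blob_radius_range[1],
                             spec$blob_radius_range[2])
      peak <- stats::runif(1, spec$blob_peak_range[1], spec$blob_peak_range[2])
      cy <- stats::runif(1, 1, spec$height)
      cx <- stats::runif(1, 1, spec$width)
      ext <- ceiling(radius + 4 * w)
      rows <- max(1, floor(cy - ext)):min(spec$height, ceiling(cy + ext))
      cols <- max(1, floor(cx - ext)):min(spec$width, ceiling(cx + ext))
      d <- sqrt(outer((rows - cy)^2, (cols - cx)^2, "+"))
      # flat interior, erf-profile edge of width w centred on the boundary
      profile <- 0.5 * (1 - erf((d - radius) / (sqrt(2) * w)))
      img[rows, cols] <- img[rows, cols] + peak * profile
      mask[rows, cols] <- mask[rows, cols] | (d <= radius)
    }
    list(image = pmin(img, 65535), mask = mask)
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}

erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

sample_int_range <- function(r) {
  lo <- as.integer(ceiling(r[1])); hi <- as.integer(floor(r[2]))
  if (hi <= lo) return(lo)
  lo + sample.int(hi - lo + 1L, 1L) - 1L
}

#' Labeled patch set
#'
#' Container for training/test examples: 84 x 84 patches of raw 16-bit
#' counts, their true defocus level, and a flag marking patches that
#' intersect foreground (blob support) — the only patches on which focus
#' is physically well-defined.
#'
#' @param patches Numeric array `patch_size x patch_size x n`.
#' @param labels Integer vector of defocus levels, `0 .. n_levels - 1`.
#' @param foreground Logical vector: does the patch intersect any blob?
#' @param scene_id Integer vector mapping each patch to its source scene.
#' @param n_levels Number of defocus classes.
#' @param seed Seed used to build the set (provenance).
#' @return An object of class `labeled_patch_set`.
#' @export
labeled_patch_set <- function(patches, labels, foreground, scene_id,
                              n_levels, seed = NA_integer_) {
  stopifnot(length(dim(patches)) == 3,
            dim(patches)[3] == length(labels),
            length(labels) == length(foreground),
            length(labels) == length(scene_id),
            all(labels >= 0), all(labels < n_levels))
  structure(list(patches = patches, labels = as.integer(labels),
                 foreground = as.logical(foreground),
                 scene_id = as.integer(scene_id),
                 n_levels = as.integer(n_levels), seed = seed),
            class = "labeled_patch_set")
}

#' @export
print.labeled_patch_set <- function(x, ...) {
  cat(sprintf("Labeled patch set: %d patches (%dx%d), %d levels, %.0f%% foreground\n",
              dim(x$patches)[3], dim(x$patches)[1], dim(x$patches)[2],
              x$n_levels, 100 * mean(x$foreground)))
  invisible(x)
}

#' Build a synthetic labeled train/test patch dataset
#'
#' Generates `n_scenes` in-focus scenes, splits them 50/50 into train and
#' test *before* any patch extraction (no scene contributes to both splits,
#' mirroring a split by imaging site), expands every scene into an 11-level
#' defocus stack, and cuts random patches from each stack image, labeled with
#' the stack level.
#'
#' @param n_scenes Number of scenes (`>= 2`); odd counts put the extra scene
#'   in the training half.
#' @param spec A [scene_spec()].
#' @param params An [optical_params()].
#' @param sensor A [sensor_model()].
#' @param patches_per_image Random crops per stack image.
#' @param seed Integer seed controlling scenes, noise and crop positions.
#' @param keep_images Also return the raw training-half stack images (as a
#'   [labeled_image_set()]) so the classifier can be trained on crops drawn
#'   afresh at every step rather than on the fixed pre-cut patches.
#' @return List with elements `train` and `test`, each a
#'   [labeled_patch_set()]; with `keep_images = TRUE` also `train_images`.
#' @export
make_dataset <- function(n_scenes, spec = scene_spec(),
                         params = optical_params(), sensor = sensor_model(),
                         patches_per_image = 8, seed = 1,
                         keep_images = FALSE) {
  stopifnot(n_scenes >= 2)
  ps <- spec$patch_size
  if (ps > spec$height || ps > spec$width) {
    stop("patch size exceeds scene dimensions", call. = FALSE)
  }
  n_train <- ceiling(n_scenes / 2)
  kernels <- lapply(seq_len(params$n_levels - 1L), function(L) {
    compute_psf(params, z = L * params$z_step)
  })
  plan <- stack_fft_plan(kernels, spec$height, spec$width)
  sets <- list(train = NULL, test = NULL)
  scene_split <- rep(c("train", "test"), c(n_train, n_scenes - n_train))
  per_scene <- params$n_levels * patches_per_image
  train_imgs <- if (keep_images) {
    array(0, c(spec$height, spec$width, n_train * params$n_levels))
  }
  train_img_labels <- integer(0)
  img_i <- 0L
  for (split in c("train", "test")) {
    ids <- which(scene_split == split)
    n_tot <- length(ids) * per_scene
    patches <- array(0, c(ps, ps, n_tot))
    labels <- integer(n_tot); fg <- logical(n_tot); sid <- integer(n_tot)
    i <- 0L
    for (s in ids) {
      scene <- make_scene(spec, seed = seed + 1000L * s)
      stack <- generate_defocus_stack(scene$image, params, sensor,
                                      seed = seed + 1000L * s + 100L,
                                      plan = plan)
      # positions drawn independently for every stack image: crop diversity
      # is what keeps a 22M-parameter network from memorizing the patches
      crops <- withr::with_seed(seed + 1000L * s + 500L, {
        data.frame(
          row = sample.int(spec$height - ps + 1L,
                           per_scene, replace = TRUE),
          col = sample.int(spec$width - ps + 1L,
                           per_scene, replace = TRUE))
      })
      if (keep_images && split == "train") {
        for (L in seq_len(params$n_levels)) {
          img_i <- img_i + 1L
          train_imgs[, , img_i] <- stack$images[[L]]
          train_img_labels[img_i] <- stack$levels[L]
        }
      }
      j <- 0L
      for (L in seq_len(params$n_levels)) {
        img <- stack$images[[L]]
        for (p in seq_len(patches_per_image)) {
          j <- j + 1L; i <- i + 1L
          r0 <- crops$row[j]; c0 <- crops$col[j]
          patches[, , i] <- img[r0:(r0 + ps - 1L), c0:(c0 + ps - 1L)]
          labels[i] <- stack$levels[L]
          fg[i] <- any(scene$mask[r0:(r0 + ps - 1L), c0:(c0 + ps - 1L)])
          sid[i] <- s
        }
      }
    }
    sets[[split]] <- labeled_patch_set(patches, labels, fg, sid,
                                       params$n_levels, seed = seed)
  }
  if (keep_images) {
    sets$train_images <- labeled_image_set(train_imgs, train_img_labels,
                                           params$n_levels, seed = seed)
  }
  sets
}

#' Labeled image set
#'
#' Whole stack images with their defocus level, used to train the
#' classifier on randomly positioned crops drawn afresh at every training
#' step — the crop diversity that pre-cut patch sets lack.
#'
#' @param images Numeric array `height x width x n`.
#' @param labels Integer defocus level per image.
#' @param n_levels Number of defocus classes.
#' @param seed Seed used to build the set (provenance).
#' @return An object of class `labeled_image_set`.
#' @export
labeled_image_set <- function(images, labels, n_levels, seed = NA_integer_) {
  stopifnot(length(dim(images)) == 3, dim(images)[3] == length(labels),
            all(labels >= 0), all(labels < n_levels))
  structure(list(images = images, labels = as.integer(labels),
                 n_levels = as.integer(n_levels), seed = seed),
            class = "labeled_image_set")
}

#' @export
print.labeled_image_set <- function(x, ...) {
  cat(sprintf("Labeled image set: %d images (%dx%d), %d levels\n",
              dim(x$images)[3], dim(x$images)[1], dim(x$images)[2],
              x$n_levels))
  invisible(x)
}
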