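#' Index a local focal-stack image collection
#'
#' Thin adapter for public benchmark collections kept on local disk (for
#' example a BBBC006v1-style layout: z-stacks of one field per imaging
#' site, the z-index encoded in the file name or in per-z directory
#' names). Nothing is downloaded; the function only scans a directory and
#' returns a manifest that the evaluation functions can consume.
#'
#' Recognized patterns, checked in order: a `_z<digits>` / `-z<digits>`
#' token in the file name, or an enclosing directory name containing
#' `z<digits>`. The site identifier is the file name with the z token
#' removed.
#'
#' @param dir Root directory containing `.tif`/`.tiff`/`.png` images.
#' @return `data.frame` with columns `path`, `site`, `z`, ordered by site
#'   and z.
#' @export
index_focal_stacks <- function(dir) {
  if (!dir.exists(dir)) stop("directory not found: ", dir, call. = FALSE)
  paths <- list.files(dir, pattern = "\\.(tif|tiff|png)$", recursive = TRUE,
                      full.names = TRUE, ignore.case = TRUE)
  if (length(paths) == 0) stop("no images under ", dir, call. = FALSE)
  base <- basename(paths)
  m <- regmatches(base, regexpr("[_-]z[0-9]+", base, ignore.case = TRUE))
  z <- rep(NA_integer_, length(paths))
  site <- base
  has_tok <- grepl("[_-]z[0-9]+", base, ignore.case = TRUE)
  z[has_tok] <- as.integer(gsub("[^0-9]", "", m))
  site[has_tok] <- sub("[_-]z[0-9]+", "", base[has_tok], ignore.case = TRUE)
  # fall back to a z-encoded parent directory (one directory per plane)
  dirtok <- grepl("z[0-9]+", basename(dirname(paths)), ignore.case = TRUE)
  use_dir <- !has_tok & dirtok
  z[use_dir] <- as.integer(gsub("[^0-9]", "",
                                basename(dirname(paths[use_dir]))))
  if (anyNA(z)) {
    stop("could not infer a z-index for ",
         sum(is.na(z)), " image(s); expected '_z<digits>' in file names ",
         "or 'z<digits>' directories", call. = FALSE)
  }
  out <- data.frame(path = paths, site = tools::file_path_sans_ext(site),
                    z = z, stringsAsFactors = FALSE)
  out[order(out$site, out$z), , drop = FALSE]
}

#' Label a focal-stack manifest with distance from best focus
#'
#' For every imaging site, loads the stack, picks the best-focus plane
#' (largest pixel standard deviation, see [select_best_focus()]) and
#' labels each plane with its absolute z-distance from it, capped at
#' `n_levels - 1`. This turns a raw focal-stack collection into ground
#' truth for the absolute-defocus evaluation.
#'
#' @param manifest Output of [index_focal_stacks()].
#' @param n_levels Number of defocus classes to cap the distance at.
#' @return The manifest with an added `level` column.
#' @export
label_by_best_focus <- function(manifest, n_levels = 11L) {
  stopifnot(all(c("path", "site", "z") %in% names(manifest)))
  manifest$level <- NA_integer_
  for (s in unique(manifest$site)) {
    rows <- which(manifest$site == s)
    stack <- lapply(manifest$path[rows], function(p) read_image(p)$pixels)
    best <- attr(select_best_focus(stack), "z_index")
    manifest$level[rows] <- pmin(abs(manifest$z[rows] -
                                       manifest$z[rows][best]),
                                 n_levels - 1L)
  }
  manifest
}
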