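#' Whole-image prediction for one image
#'
#' Convenience wrapper: tiles the image, predicts every patch and
#' aggregates with certainty weighting.
#'
#' @param model A trained model.
#' @param image Numeric matrix of raw counts (or `image_record`).
#' @return List with `patches` (the per-patch prediction frame) and
#'   `image` (the [aggregate_image()] result).
#' @export
predict_image <- function(model, image) {
  if (inherits(image, "image_record")) image <- image$pixels
  pp <- predict_image_patches(model, image)
  list(patches = pp, image = aggregate_image(pp))
}

#' End-to-end synthetic defocus study
#'
#' The package's self-contained benchmark: generate synthetic nuclei-like
#' scenes, expand each into an 11-level defocus stack under the stated
#' optics and sensor noise, split scenes 50/50 into train and test before
#' patch extraction, train the ordinal patch classifier with photometric
#' augmentation, and measure the confusion structure on held-out
#' *foreground* patches (background patches carry no focus information).
#'
#' @param n_scenes Number of scenes (half train, half test).
#' @param seed Master seed for scenes, noise, crops and training.
#' @param spec,params,sensor Generator, optics and sensor settings.
#' @param patches_per_image Random test crops per stack image (training
#'   draws its crops afresh each step from the whole stack images).
#' @param cfg Training configuration; default [desk_train_config()].
#' @return List of class `focus_study`: `model`, `train`, `test`
#'   (patch sets), `train_images` (the stack images the model trained on),
#'   `confusion` (foreground test patches), `within_one`
#'   (within-one-level accuracy), `accuracy` (exact-level accuracy),
#'   `test_probs`.
#' @export
run_defocus_study <- function(n_scenes = 24, seed = 7,
                              spec = scene_spec(),
                              params = optical_params(),
                              sensor = sensor_model(),
                              patches_per_image = 8,
                              cfg = desk_train_config(seed = seed)) {
  data <- make_dataset(n_scenes, spec, params, sensor,
                       patches_per_image = patches_per_image, seed = seed,
                       keep_images = TRUE)
  model <- train_focus_model(data$train_images, model_spec(params$n_levels),
                             cfg)
  keep <- which(data$test$foreground)
  probs <- predict_patches(model, data$test$patches[, , keep, drop = FALSE])
  pred <- max.col(probs, ties.method = "first") - 1L
  cm <- confusion(data$test$labels[keep], pred, params$n_levels)
  structure(list(model = model, train = data$train,
                 train_images = data$train_images, test = data$test,
                 confusion = cm,
                 within_one = within_k_accuracy(cm, 1L),
                 accuracy = within_k_accuracy(cm, 0L),
                 test_probs = probs),
            class = "focus_study")
}

#' @export
print.focus_study <- function(x, ...) {
  cat(sprintf(
    "Synthetic defocus study: %d held-out foreground patches, %.1f%% within one level (%.1f%% exact)\n",
    sum(x$confusion), 100 * x$within_one, 100 * x$accuracy))
  invisible(x)
}
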