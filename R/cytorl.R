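# The user-facing fit interface, in the classic R modelling idiom: one
# fitting function returning a classed object with print / summary /
# predict / plot methods.

#' Fit the RL-reweighted cytology classifier
#'
#' Splits the dataset 70/15/15 (stratified), trains the hybrid
#' CNN-transformer-supporter classifier (stage 1) and, optionally, the
#' DQN-driven class-reweighting stage (stage 2), then evaluates on the held
#' out test set.
#'
#' @param data a `cyto_manifest` (e.g. from [generate_dataset()] or
#'   [load_image_tree()]) or a path to a class-labelled image directory tree
#' @param config run configuration, see [default_config()]
#' @param stages `1` for supervised training only, `2` to add the RL
#'   reweighting stage (default)
#' @return an object of class `cytorl` with components `model`, `config`,
#'   `splits`, `stage1`/`stage2` checkpoints, `metrics` (test-set
#'   `metrics_report`), and `weights` (final per-class loss weights)
#' @export
cytorl <- function(data, config = default_config(), stages = 2L) {
  validate_config(config)
  manifest <- if (is.character(data)) load_image_tree(data) else data
  stopifnot(inherits(manifest, "cyto_manifest"))
  C <- length(manifest_counts(manifest))
  splits <- stratified_split(manifest,
                             split_spec(seed = derive_seed(config$seed, 1)))
  m <- build_model(config, n_classes = C)
  cp1 <- train_stage1(m, splits, config)
  cp2 <- NULL
  if (stages >= 2L && config$training$stage2_epochs > 0L)
    cp2 <- train_stage2(cp1, m, splits, config)
  final <- cp2 %||% cp1
  model_restore(m, final$state)
  metrics <- evaluate_model(m, splits$test, config)
  structure(list(model = m, config = config, splits = splits,
                 stage1 = cp1, stage2 = cp2, metrics = metrics,
                 weights = if (!is.null(cp2)) cp2$final_weights
                 else rep(1, C),
                 class_names = attr(manifest, "class_names")),
            class = "cytorl")
}

#' @export
print.cytorl <- function(x, ...) {
  cat("RL-reweighted cytology classifier\n")
  cat(sprintf("  classes: %s\n", paste(x$class_names, collapse = ", ")))
  cat(sprintf("  parameters: %d | stages trained: %s\n",
              x$model$n_params, if (is.null(x$stage2)) "1" else "1+2"))
  cat(sprintf("  test accuracy %.4f | macro-F1 %.4f | G-means %.4f\n",
              x$metrics$accuracy, x$metrics$macro_f1, x$metrics$g_means))
  if (!is.null(x$stage2))
    cat(sprintf("  final class weights: %s\n",
                paste(sprintf("%.3f", x$weights), collapse = ", ")))
  invisible(x)
}

#' @export
summary.cytorl <- function(object, ...) {
  print(object)
  cat("\nPer-class test metrics:\n")
  print(object$metrics$per_class, row.names = FALSE)
  cat("\nTraining history (last epochs):\n")
  h <- rbind(object$stage1$history,
             if (!is.null(object$stage2)) object$stage2$history)
  print(utils::tail(h, 5), row.names = FALSE)
  invisible(object)
}

#' Predict classes or probabilities for new images
#'
#' @param object a fitted [cytorl()] model
#' @param newdata a `cyto_manifest`, a directory path, or a (n, H, W) array
#'   of preprocessed images
#' @param type `"class"` (default) or `"prob"`
#' @param ... unused
#' @return factor of predicted class names, or a probability matrix
#' @export
predict.cytorl <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  if (is.character(newdata)) newdata <- load_image_tree(newdata)
  x <- if (inherits(newdata, "cyto_manifest"))
    load_images(newdata, preproc_config(object$config$data$image_size))$x
  else newdata
  probs <- model_predict(object$model, x)
  colnames(probs) <- object$class_names
  if (type == "prob") return(probs)
  factor(object$class_names[max.col(probs, ties.method = "first")],
         levels = object$class_names)
}

#' Plot training curves and the class-weight trajectory
#'
#' @param x a fitted [cytorl()] model
#' @param ... unused
#' @export
plot.cytorl <- function(x, ...) {
  h <- rbind(x$stage1$history,
             if (!is.null(x$stage2)) x$stage2$history)
  has_traj <- !is.null(x$stage2$weight_trajectory)
  op <- graphics::par(mfrow = c(1, if (has_traj) 2 else 1))
  on.exit(graphics::par(op))
  graphics::plot(h$epoch, h$val_macro_f1, type = "l", col = "steelblue",
                 xlab = "epoch", ylab = "validation macro-F1",
                 main = "training progress", ylim = c(0, 1))
  graphics::lines(h$epoch, h$val_accuracy, col = "grey50", lty = 2)
  if (!is.null(x$stage2))
    graphics::abline(v = x$stage1$history$epoch[nrow(x$stage1$history)] + 0.5,
                     lty = 3)
  graphics::legend("bottomright", c("macro-F1", "accuracy"),
                   col = c("steelblue", "grey50"), lty = c(1, 2), bty = "n")
  if (has_traj) {
    tr <- x$stage2$weight_trajectory
    wcols <- grep("^w[0-9]+$", names(tr), value = TRUE)
    graphics::matplot(tr$step, tr[, wcols], type = "l", lty = 1,
                      xlab = "stage-2 step", ylab = "class weight",
                      main = "RL weight trajectory")
    graphics::legend("topleft", wcols, col = seq_along(wcols), lty = 1,
                     bty = "n")
  }
  invisible(x)
}

#' Residuals of the fitted classifier on its test split
#'
#' Defined as 1 - predicted probability of the true class, per test sample.
#' @param object a fitted [cytorl()] model
#' @param ... unused
#' @return numeric vector
#' @export
residuals.cytorl <- function(object, ...) {
  dat <- load_images(object$splits$test,
                     preproc_config(object$config$data$image_size))
  probs <- model_predict(object$model, dat$x)
  1 - probs[cbind(seq_along(dat$y), dat$y)]
}
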