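# S3 methods for fitted agents.

#' @export
print.bias3d <- function(x, ...) {
  cat("Attentional search agent (dual what/where pathways)\n")
  cat(sprintf("  classes: %d (+ background), input channels: %d, preset: %s\n",
              x$config$n_classes, x$config$input_channels, x$config$preset))
  cat(sprintf("  trainable parameters: %s\n",
              format(count_params(x$model), big.mark = ",")))
  cat(sprintf("  trained: %d epochs x %d cubes (%d validation cubes)\n",
              x$tcfg$epochs, x$n_train, x$n_val))
  last <- x$curves[nrow(x$curves), ]
  cat(sprintf("  final mean reward/step: %.3f", last$mean_reward))
  if (!is.na(last$val_accuracy))
    cat(sprintf(", best val search accuracy: %.3f",
                max(x$curves$val_accuracy, na.rm = TRUE)))
  cat("\n")
  invisible(x)
}

#' @export
summary.bias3d <- function(object, ...) {
  tab <- param_table(object$model)
  out <- list(param_table = tab, total_params = sum(tab$n),
              curves = object$curves, config = object$config)
  class(out) <- "summary.bias3d"
  out
}

#' @export
print.summary.bias3d <- function(x, ...) {
  cat("Per-layer trainable parameters:\n")
  print(x$param_table, row.names = FALSE)
  cat(sprintf("Total: %s\n\n", format(x$total_params, big.mark = ",")))
  cat("Training curves:\n")
  print(x$curves, row.names = FALSE)
  invisible(x)
}

#' @export
coef.bias3d <- function(object, ...) object$model$params

#' Search new cubes with a fitted agent
#'
#' @param object a fitted `bias3d`.
#' @param newdata list of [cube_scene()] objects.
#' @param type `"search"` for a per-cube results data frame,
#'   `"metrics"` for the aggregate [evaluate_cubes()] list.
#' @param threshold testing confidence threshold (defaults to the one used
#'   during fitting).
#' @param seed integer seed for the start azimuths.
#' @param ... passed on to [evaluate_cubes()].
#' @return data frame or metrics list, per `type`.
#' @export
predict.bias3d <- function(object, newdata, type = c("search", "metrics"),
                           threshold = NULL, seed = 1L, ...) {
  type <- match.arg(type)
  threshold <- threshold %||% object$test_threshold
  ev <- evaluate_cubes(newdata, object, threshold = threshold,
                       max_steps = object$tcfg$timesteps_per_cube,
                       jump = object$tcfg$jump_length, seed = seed, ...)
  if (type == "metrics") return(ev)
  data.frame(
    target_class = vapply(newdata, `[[`, integer(1), "target_class"),
    predicted_class = vapply(ev$results, `[[`, integer(1), "predicted_class"),
    success = vapply(ev$results, `[[`, logical(1), "success"),
    steps = vapply(ev$results, `[[`, integer(1), "steps_taken"),
    terminated_by = vapply(ev$results, `[[`, character(1), "terminated_by"))
}

#' Plot training curves
#'
#' Mean per-step reward and validation search accuracy against epochs.
#'
#' @param x a fitted `bias3d`.
#' @param ... ignored.
#' @export
plot.bias3d <- function(x, ...) {
  cv <- x$curves
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(cv$epoch, cv$mean_reward, type = "b", pch = 16,
                 xlab = "epoch", ylab = "mean reward / step",
                 main = "reward")
  if (!all(is.na(cv$val_accuracy)))
    graphics::plot(cv$epoch, cv$val_accuracy, type = "b", pch = 16,
                   ylim = c(0, 1), xlab = "epoch", ylab = "search accuracy",
                   main = "validation")
  invisible(x)
}
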