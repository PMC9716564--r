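# Inference-time search: start at a random azimuth, run the agent greedily
# (no exploration) and stop as soon as the classifier's confidence crosses
# the testing threshold with a non-background argmax; score success, steps
# and trajectories.

#' Stub agents for evaluation baselines
#'
#' `oracle_agent()` reads the scene ground truth and is always confidently
#' correct at step 0 (an upper-bound sanity stub). `random_agent(pre)`
#' couples uniformly random camera actions with the pretrained feed-forward
#' classifier's probabilities (the no-learned-policy baseline).
#'
#' @param pre a `bias3d_pretrain` classifier.
#' @return objects dispatched on by [run_search()].
#' @export
oracle_agent <- function() structure(list(), class = "bias3d_oracle")

#' @rdname oracle_agent
#' @export
random_agent <- function(pre) {
  stopifnot(inherits(pre, "bias3d_pretrain"))
  structure(list(pre = pre), class = "bias3d_random")
}

#' Run one inference-time search on a cube
#'
#' Pure exploitation: from a random start azimuth the agent repeatedly
#' renders, extracts the glimpse, runs one forward step, and stops as soon
#' as the maximum class probability reaches the testing threshold with a
#' non-background argmax; otherwise it moves the camera by its greedy
#' action (confidence about the background class alone never ends the
#' search - there is nothing to report there). If the threshold is never
#' crossed that way the search ends after `max_steps` camera moves with
#' `success = FALSE`.
#'
#' @param scene a [cube_scene()].
#' @param model a fitted `bias3d` object, a `bias3d_net`, or one of the
#'   stub agents ([oracle_agent()], [random_agent()]).
#' @param threshold testing confidence threshold in (0, 1) (0.95 for
#'   MNIST-style cubes, 0.85 for sketch-style cubes in the published setup).
#' @param max_steps maximum number of camera moves (default 50, the
#'   training episode length).
#' @param jump camera jump length in degrees.
#' @param seed optional integer seed (start azimuth; random-agent actions).
#' @param race_threshold decision threshold of the action race (see
#'   [select_action()]); default 0.85.
#' @param render_cfg,glimpse_cfg rendering and glimpse settings.
#' @return object of class `bias3d_search`: list with `trajectory` (data
#'   frame of theta, action, max_prob, argmax_class), `probs` (step x class
#'   matrix), `steps_taken`, `predicted_class`, `success`, `terminated_by`.
#' @export
run_search <- function(scene, model, threshold = 0.85, max_steps = 50L,
                       jump = 12, seed = NULL, race_threshold = 0.85,
                       render_cfg = render_config(),
                       glimpse_cfg = glimpse_config()) {
  stopifnot(threshold > 0, threshold < 1)
  if (inherits(model, "bias3d")) model <- model$model
  kind <- if (inherits(model, "bias3d_oracle")) "oracle"
          else if (inherits(model, "bias3d_random")) "random"
          else if (inherits(model, "bias3d_net")) "net"
          else stopf("run_search: unsupported model class")
  n_classes <- if (kind == "net") model$config$n_classes
               else if (kind == "random") model$pre$config$n_classes
               else scene$target_class + 1L
  gf <- glimpse_provider(scene, render_cfg, glimpse_cfg)
  with_seed(seed, {
    # uniform over the orbit positions reachable with this jump length
    # (the agent's state space); falls back to continuous uniform when the
    # jump does not divide the orbit
    theta <- if (360 %% jump == 0) jump * (sample.int(360 %/% jump, 1L) - 1L)
             else stats::runif(1, 0, 360)
    st <- if (kind == "net") reset_state(model$config) else NULL
    steps_taken <- 0L
    prev <- NULL
    rows <- list(); probs <- list()
    repeat {
      gm <- gf(theta)
      if (kind == "net") {
        out <- .cpp_step(model$params, model$config, gm, theta, st)
        st <- out$state
        p <- as.numeric(out$p); q <- as.numeric(out$q)
        act <- select_action(q, epsilon = 0, prev_action = prev,
                             race_threshold = race_threshold)
        prev <- act
      } else if (kind == "random") {
        p <- pretrain_predict(model$pre, gm)
        act <- sample.int(3L, 1L)
      } else {
        p <- onehot(scene$target_class, n_classes + 1L)
        act <- 3L
      }
      amax <- which.max(p) - 1L
      rows[[length(rows) + 1L]] <-
        data.frame(theta = theta, action = act, max_prob = max(p),
                   argmax_class = amax)
      probs[[length(probs) + 1L]] <- p
      if (max(p) >= threshold && amax != n_classes) {
        return(structure(list(
          trajectory = do.call(rbind, rows),
          probs = do.call(rbind, probs),
          steps_taken = steps_taken,
          predicted_class = amax,
          success = amax == scene$target_class,
          terminated_by = "threshold"), class = "bias3d_search"))
      }
      if (steps_taken >= max_steps) {
        return(structure(list(
          trajectory = do.call(rbind, rows),
          probs = do.call(rbind, probs),
          steps_taken = steps_taken,
          predicted_class = amax,
          success = FALSE,
          terminated_by = "max_steps"), class = "bias3d_search"))
      }
      theta <- step_camera(theta, act, jump)
      steps_taken <- steps_taken + 1L
    }
  })
}

#' Evaluate search performance over a set of cubes
#'
#' Runs [run_search()] on every cube with derived seeds and aggregates
#' search accuracy (fraction of successful searches), step statistics,
#' per-class accuracy, and the classification accuracy among
#' threshold-terminated searches.
#'
#' @param cubes list of [cube_scene()] objects.
#' @param model as in [run_search()].
#' @param threshold,max_steps,jump,render_cfg,glimpse_cfg as in
#'   [run_search()].
#' @param seed integer seed (one child seed per cube).
#' @return list with `accuracy`, `mean_steps`, `median_steps`,
#'   `class_accuracy_at_stop`, `per_class` (data frame) and `results`
#'   (the individual `bias3d_search` objects).
#' @export
evaluate_cubes <- function(cubes, model, threshold = 0.85, max_steps = 50L,
                           jump = 12, seed = 1L,
                           render_cfg = render_config(),
                           glimpse_cfg = glimpse_config()) {
  stopifnot(length(cubes) > 0)
  seeds <- derive_seeds(seed, length(cubes))
  res <- lapply(seq_along(cubes), function(i)
    run_search(cubes[[i]], model, threshold = threshold,
               max_steps = max_steps, jump = jump, seed = seeds[i],
               render_cfg = render_cfg, glimpse_cfg = glimpse_cfg))
  succ <- vapply(res, `[[`, logical(1), "success")
  stp <- vapply(res, `[[`, integer(1), "steps_taken")
  term <- vapply(res, `[[`, character(1), "terminated_by")
  pred <- vapply(res, `[[`, integer(1), "predicted_class")
  tgt <- vapply(cubes, `[[`, integer(1), "target_class")
  at_stop <- term == "threshold"
  per_class <- aggregate(list(accuracy = succ), by = list(class = tgt), mean)
  list(accuracy = mean(succ),
       mean_steps = mean(stp), median_steps = stats::median(stp),
       class_accuracy_at_stop =
         if (any(at_stop)) mean(pred[at_stop] == tgt[at_stop]) else NA_real_,
       per_class = per_class,
       results = res)
}

#' Plot a search trace
#'
#' Writes one PNG per step: the rendered 75x100 view with the three
#' concentric red glimpse windows overlaid, beside the predicted class
#' probabilities against the ground truth.
#'
#' @param result a `bias3d_search` from [run_search()].
#' @param scene the [cube_scene()] the search ran on.
#' @param out_path directory for the PNG files (created if missing).
#' @param render_cfg,glimpse_cfg settings matching the search.
#' @return invisibly, the written file paths.
#' @export
trace_plot <- function(result, scene, out_path,
                       render_cfg = render_config(),
                       glimpse_cfg = glimpse_config()) {
  dir.create(out_path, showWarnings = FALSE, recursive = TRUE)
  H <- render_cfg$view_height; W <- render_cfg$view_width
  ctr <- c(H %/% 2L, W %/% 2L)
  n_steps <- nrow(result$trajectory)
  n_out <- ncol(result$probs)
  truth <- onehot(scene$target_class, n_out)
  files <- character(n_steps)
  for (t in seq_len(n_steps)) {
    th <- result$trajectory$theta[t]
    v <- render(scene, camera_pose(th), render_cfg)
    img <- if (dim(v)[3] == 1L) array(rep(v, 3), c(H, W, 3)) else v
    f <- file.path(out_path, sprintf("step_%03d.png", t))
    grDevices::png(f, width = 720, height = 320)
    graphics::par(mfrow = c(1, 2), mar = c(3, 3, 2, 1))
    graphics::plot(NA, xlim = c(0, W), ylim = c(0, H), asp = 1,
                   xlab = "", ylab = "", axes = FALSE,
                   main = sprintf("t = %d, theta = %.0f", t - 1L, th))
    graphics::rasterImage(img, 0, 0, W, H, interpolate = FALSE)
    for (sz in glimpse_cfg$window_sizes) {
      rb <- crop_bounds(ctr[1], sz); cb <- crop_bounds(ctr[2], sz)
      graphics::rect(cb["lo"], H - rb["hi"], cb["hi"], H - rb["lo"],
                     border = "red", lwd = 2)
    }
    graphics::barplot(rbind(result$probs[t, ], truth), beside = TRUE,
                      names.arg = c(seq_len(n_out - 1L) - 1L, "bg"),
                      col = c("steelblue", "darkgreen"),
                      ylim = c(0, 1), main = "predicted vs truth")
    grDevices::dev.off()
    files[t] <- f
  }
  invisible(files)
}
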