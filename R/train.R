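# End-to-end training: episodes rolled in the cube world, a {0,1} reward
# from confident correct classification, Q-learning with a periodically
# synced target network, and one backward pass per episode through the
# unrolled recurrences (cross-entropy + TD mean-square loss, Adam, L2
# weight decay, global-norm gradient clipping).

#' Trainer configuration
#'
#' Defaults follow the published hyperparameters: learning rate 1e-4,
#' discount 0.43, reward threshold (lambda) 0.85, L2 factor 0.1, exploration
#' epsilon starting at 0.99 with decay 0.999 per episode floored at 0.1,
#' 50 timesteps per cube, jump length 12 degrees.
#'
#' @param lr Adam learning rate.
#' @param gamma discount factor in `[0, 1)`.
#' @param lambda_threshold classification-confidence threshold of the reward.
#' @param l2_factor L2 regularization factor (optimizer weight decay on
#'   weight matrices; biases are not decayed).
#' @param epsilon_start,epsilon_decay,epsilon_min exploration schedule
#'   (decay applied once per episode).
#' @param timesteps_per_cube episode length.
#' @param epochs passes over the training cubes.
#' @param jump_length camera jump in degrees per move.
#' @param target_sync_every hard-sync period of the target network, in
#'   episodes.
#' @param mse_all_actions if `TRUE` the TD term averages over all three
#'   actions instead of only the taken one (default `FALSE`: standard
#'   Q-learning on the taken action).
#' @param bg_ce_weight weight of background-labelled steps in the episode
#'   cross-entropy (default 0.25). An orbiting camera sees roughly three
#'   background views per target view; the same class-imbalance correction
#'   that pretraining applies by subsampling is applied here by weighting,
#'   so end-to-end training does not erode the classifier's on-face
#'   confidence. Set to 1 for unweighted cross-entropy.
#' @param seed integer seed.
#' @return object of class `trainer_config`.
#' @export
trainer_config <- function(lr = 1e-4, gamma = 0.43, lambda_threshold = 0.85,
                           l2_factor = 0.1, epsilon_start = 0.99,
                           epsilon_decay = 0.999, epsilon_min = 0.1,
                           timesteps_per_cube = 50L, epochs = 25L,
                           jump_length = 12, target_sync_every = 10L,
                           mse_all_actions = FALSE, bg_ce_weight = 0.25,
                           seed = 1L) {
  if (gamma < 0 || gamma >= 1) stopf("trainer_config: gamma must be in [0,1)")
  if (epsilon_start < epsilon_min)
    stopf("trainer_config: epsilon_start below epsilon_min")
  structure(list(lr = lr, gamma = gamma, lambda_threshold = lambda_threshold,
                 l2_factor = l2_factor, epsilon_start = epsilon_start,
                 epsilon_decay = epsilon_decay, epsilon_min = epsilon_min,
                 timesteps_per_cube = as.integer(timesteps_per_cube),
                 epochs = as.integer(epochs), jump_length = jump_length,
                 target_sync_every = as.integer(target_sync_every),
                 mse_all_actions = mse_all_actions,
                 bg_ce_weight = bg_ce_weight,
                 seed = as.integer(seed)),
            class = "trainer_config")
}

#' Classification reward
#'
#' Reward 1 if and only if the classifier's argmax matches the desired class
#' and its confidence reaches the threshold lambda; else 0.
#'
#' @param p predicted class-probability vector (on the simplex).
#' @param d desired one-hot vector (same length).
#' @param lambda_threshold confidence threshold.
#' @return 0 or 1.
#' @export
compute_reward <- function(p, d, lambda_threshold = 0.85) {
  if (length(p) != length(d))
    stopf("compute_reward: p and d lengths differ")
  as.numeric(which.max(p) == which.max(d) && max(p) >= lambda_threshold)
}

#' Epsilon-greedy race-model action selection
#'
#' With probability epsilon a uniformly random action is taken
#' (exploration). Otherwise the three responses race: the Q-values are
#' passed through a softmax, and an action is emitted as soon as its
#' probability crosses the decision threshold lambda - ties broken by
#' lowest index. When no response separates from the field within the
#' single evaluation (all probabilities below lambda), the previously
#' winning response keeps running and is repeated; with no previous action
#' the plain argmax is used. This persistence is what race models predict
#' for undecided single-look trials, and it yields the continuous,
#' non-alternating camera movements characteristic of the trained agent.
#'
#' @param q numeric 3-vector of Q-values.
#' @param epsilon exploration probability in `[0, 1]`.
#' @param seed optional integer seed.
#' @param prev_action previously executed action index, or `NULL`.
#' @param race_threshold decision threshold lambda of the race
#'   (default 0.85, the reward threshold).
#' @return action index in 1..3 (1 = right, 2 = left, 3 = stay).
#' @export
select_action <- function(q, epsilon, seed = NULL, prev_action = NULL,
                          race_threshold = 0.85) {
  stopifnot(epsilon >= 0, epsilon <= 1)
  with_seed(seed, {
    if (stats::runif(1) < epsilon) sample.int(length(q), 1L)
    else {
      p <- softmax(q)
      if (is.null(prev_action) || max(p) >= race_threshold) which.max(p)
      else as.integer(prev_action)
    }
  })
}

#' Temporal-difference error
#'
#' `TD = (r + gamma * max(q_next_target)) - q_taken`.
#'
#' @param r immediate reward.
#' @param q_next_target target-network Q-values of the next state.
#' @param q_taken online Q-value of the action taken.
#' @param gamma discount factor.
#' @return scalar TD error.
#' @export
td_error <- function(r, q_next_target, q_taken, gamma) {
  r + gamma * max(q_next_target) - q_taken
}

#' Combined episode loss
#'
#' Cross-entropy of the predicted class probabilities against the desired
#' one-hot labels (log guarded by 1e-12), averaged over steps, plus the mean
#' squared TD error. The L2 penalty is not part of this value; it enters
#' through the optimizer's weight decay.
#'
#' @param class_probs matrix (steps x classes) or single probability vector.
#' @param target_onehot matching one-hot matrix/vector.
#' @param td_errors numeric vector of TD errors.
#' @return list with `total`, `ce` and `mse` (total = ce + mse).
#' @export
total_loss <- function(class_probs, target_onehot, td_errors) {
  p <- rbind(class_probs); d <- rbind(target_onehot)
  ce <- mean(-rowSums(d * log(p + 1e-12)))
  mse <- mean(td_errors^2)
  list(total = ce + mse, ce = ce, mse = mse)
}

#' Hard-sync the target network
#'
#' @param model the online `bias3d_net`.
#' @param target_model ignored (present for call-site symmetry); the new
#'   target is a full copy of the online parameters.
#' @return the synced target network.
#' @export
sync_target <- function(model, target_model = NULL) {
  model
}

# ---- Adam -----------------------------------------------------------------

adam_init <- function(pr) {
  list(m = lapply(pr, function(x) 0 * x), v = lapply(pr, function(x) 0 * x),
       t = 0L)
}

# One Adam update; weight decay on every tensor except biases (*_b).
adam_step <- function(pr, gr, opt, lr, weight_decay = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  b1t <- 1 - beta1^opt$t
  b2t <- 1 - beta2^opt$t
  for (nm in names(pr)) {
    g <- gr[[nm]]
    if (weight_decay > 0 && !endsWith(nm, "_b")) g <- g + weight_decay * pr[[nm]]
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g * g
    pr[[nm]] <- pr[[nm]] - lr * (opt$m[[nm]] / b1t) /
      (sqrt(opt$v[[nm]] / b2t) + eps)
  }
  list(params = pr, opt = opt)
}

clip_grads <- function(gr, max_norm = 5) {
  nrm <- sqrt(sum(vapply(gr, function(g) sum(g * g), numeric(1))))
  if (is.finite(nrm) && nrm > max_norm) gr <- lapply(gr, `*`, max_norm / nrm)
  gr
}

# ---- episode machinery ----------------------------------------------------

# View-dependent desired label (0-based; n = background) by the +/-45 rule.
view_label <- function(theta, scene, n_classes) {
  if (abs(relative_offset(theta, scene)) <= 45) scene$target_class
  else n_classes
}

onehot <- function(idx0, n_out) {
  v <- numeric(n_out); v[idx0 + 1L] <- 1; v
}

# Default glimpse provider: render the scene at theta and extract a glimpse,
# memoised per (rounded) theta within one closure.
glimpse_provider <- function(scene, render_cfg = render_config(),
                             glimpse_cfg = glimpse_config()) {
  cache <- new.env(parent = emptyenv())
  g <- glimpse_cfg$out_size
  function(theta) {
    key <- sprintf("%.4f", wrap_theta(theta))
    got <- cache[[key]]
    if (is.null(got)) {
      v <- render(scene, camera_pose(theta), render_cfg)
      gl <- extract_glimpse(v, glimpse_cfg)
      got <- matrix(gl, g * g, dim(gl)[3])
      cache[[key]] <- got
    }
    got
  }
}

# Roll one episode and return the trajectory with online caches.
# Exploration and the start azimuth consume the ambient RNG stream.
rollout_episode <- function(pr, pr_target, cfg, scene, tcfg, glimpse_fn,
                            epsilon) {
  T_ <- tcfg$timesteps_per_cube
  jump <- tcfg$jump_length
  theta <- if (360 %% jump == 0) jump * sample.int(360 %/% jump, 1L) - jump
           else stats::runif(1, 0, 360)
  st_on <- reset_state(cfg); st_tg <- reset_state(cfg)
  aux_on <- make_aux(pr); aux_tg <- make_aux(pr_target)
  steps <- vector("list", T_ + 1L)
  prev <- NULL
  for (t in seq_len(T_ + 1L)) {
    gm <- glimpse_fn(theta)
    on <- model_step(pr, cfg, gm, theta, st_on, aux_on)
    tg <- model_step(pr_target, cfg, gm, theta, st_tg, aux_tg)
    st_on <- on$state; st_tg <- tg$state
    stp <- list(gm = gm, theta = theta, q = on$q, p = on$p,
                q_target = tg$q, cache = on$cache,
                label = view_label(theta, scene, cfg$n_classes))
    if (t <= T_) {
      stp$action <- select_action(on$q, epsilon, prev_action = prev,
                                  race_threshold = tcfg$lambda_threshold)
      prev <- stp$action
      theta <- step_camera(theta, stp$action, jump)
    }
    steps[[t]] <- stp
  }
  steps
}

# Loss and parameter gradients of a rolled-out episode (BPTT over all T
# steps; the trailing reward-only forward is excluded). Returns grads in
# the same named layout as the parameters.
episode_backward <- function(pr, cfg, steps, tcfg, d_target) {
  T_ <- length(steps) - 1L
  td <- numeric(T_); rew <- numeric(T_)
  for (t in seq_len(T_)) {
    rew[t] <- compute_reward(as.numeric(steps[[t + 1L]]$p), d_target,
                             tcfg$lambda_threshold)
    td[t] <- td_error(rew[t], as.numeric(steps[[t + 1L]]$q_target),
                      steps[[t]]$q[1, steps[[t]]$action], tcfg$gamma)
  }
  P <- t(vapply(seq_len(T_), function(t) as.numeric(steps[[t]]$p),
                numeric(cfg$n_out)))
  D <- t(vapply(seq_len(T_), function(t) onehot(steps[[t]]$label, cfg$n_out),
                numeric(cfg$n_out)))
  # background steps down-weighted in the CE (class-imbalance correction)
  wts <- ifelse(vapply(steps[seq_len(T_)], `[[`, integer(1), "label") ==
                  cfg$n_classes, tcfg$bg_ce_weight, 1)
  wsum <- sum(wts)
  ce <- sum(wts * -rowSums(D * log(P + 1e-12))) / wsum
  mse <- mean(td^2)
  loss <- list(total = ce + mse, ce = ce, mse = mse)
  acc <- new.env(parent = emptyenv())
  for (nm in names(pr)) acc[[nm]] <- 0 * pr[[nm]]
  carry <- zero_carry(cfg)
  for (t in rev(seq_len(T_))) {
    gz <- matrix(wts[t] * (P[t, ] - D[t, ]) / wsum, 1L)
    gq <- matrix(0, 1L, 3L)
    if (tcfg$mse_all_actions) {
      # TD recomputed per action against the same bootstrap target
      qa <- as.numeric(steps[[t]]$q)
      tda <- rew[t] + tcfg$gamma * max(as.numeric(steps[[t + 1L]]$q_target)) - qa
      gq[1, ] <- -2 * tda / (3 * T_)
    } else {
      gq[1, steps[[t]]$action] <- -2 * td[t] / T_
    }
    carry <- model_step_bwd(pr, cfg, steps[[t]]$cache, gz, gq, carry, acc)
  }
  grads <- lapply(stats::setNames(nm = names(pr)), function(nm) acc[[nm]])
  list(grads = grads, loss = loss, td = td, reward = rew)
}

#' Train on one cube episode
#'
#' Rolls exactly `timesteps_per_cube` steps from a random start azimuth:
#' render, glimpse, forward (online and target nets), epsilon-greedy action,
#' camera step, classification reward from the next state's class
#' probabilities, TD error against the target network. One backward pass
#' through the unrolled episode, gradient clipping (global norm 5), one Adam
#' update with L2 weight decay. The recurrent state is reset at the episode
#' start; epsilon is decayed once per episode by the caller ([bias3d_fit()])
#' or here if `decay_epsilon = TRUE`.
#'
#' @param scene a [cube_scene()].
#' @param model online `bias3d_net`.
#' @param target_model target `bias3d_net` (see [sync_target()]).
#' @param tcfg a [trainer_config()].
#' @param opt Adam state from a previous call, or `NULL` to initialise.
#' @param epsilon current exploration rate.
#' @param seed optional integer seed for the episode's randomness.
#' @param glimpse_fn optional memoised glimpse provider (defaults to
#'   rendering `scene` on demand).
#' @param decay_epsilon decay epsilon here (default `TRUE`).
#' @param engine `"cpp"` (compiled rollout + BPTT, the default) or `"r"`
#'   (the pure-R reference path; identical math, used by the equivalence
#'   tests).
#' @return list with updated `model`, `opt`, `epsilon`, and `metrics`
#'   (total reward, loss components, trajectory of azimuths/actions).
#' @export
train_episode <- function(scene, model, target_model, tcfg, opt = NULL,
                          epsilon = tcfg$epsilon_start, seed = NULL,
                          glimpse_fn = NULL, decay_epsilon = TRUE,
                          engine = c("cpp", "r")) {
  if (is.null(target_model)) stopf("train_episode: target_model is required")
  engine <- match.arg(engine)
  cfg <- model$config
  if (is.null(glimpse_fn)) glimpse_fn <- glimpse_provider(scene)
  if (is.null(opt)) opt <- adam_init(model$params)
  T_ <- tcfg$timesteps_per_cube
  jump <- tcfg$jump_length
  if (engine == "cpp" && 360 %% jump == 0) {
    n_grid <- 360L %/% as.integer(jump)
    gl <- lapply(seq_len(n_grid) - 1L, function(i) glimpse_fn(i * jump))
    labels <- vapply(seq_len(n_grid) - 1L, function(i)
      view_label(i * jump, scene, cfg$n_classes), integer(1))
    res <- with_seed(seed, {
      start_idx <- sample.int(n_grid, 1L) - 1L
      .cpp_episode(model$params, target_model$params, cfg, gl, labels,
                   start_idx, scene$target_class, T_, epsilon, tcfg$gamma,
                   tcfg$lambda_threshold, tcfg$mse_all_actions,
                   tcfg$bg_ce_weight, integer(0))
    })
    bk <- list(grads = res$grads,
               loss = list(total = res$loss, ce = res$ce, mse = res$mse),
               reward = res$reward)
    thetas <- res$theta_idx[seq_len(T_)] * jump
    actions <- res$actions
  } else {
    steps <- with_seed(seed,
      rollout_episode(model$params, target_model$params, cfg, scene, tcfg,
                      glimpse_fn, epsilon))
    d_target <- onehot(scene$target_class, cfg$n_out)
    bk <- episode_backward(model$params, cfg, steps, tcfg, d_target)
    thetas <- vapply(steps[seq_len(T_)], `[[`, numeric(1), "theta")
    actions <- vapply(steps[seq_len(T_)], `[[`, integer(1), "action")
  }
  gr <- clip_grads(bk$grads, 5)
  up <- adam_step(model$params, gr, opt, tcfg$lr, tcfg$l2_factor)
  model$params <- up$params
  if (decay_epsilon)
    epsilon <- max(epsilon * tcfg$epsilon_decay, tcfg$epsilon_min)
  list(model = model, opt = up$opt, epsilon = epsilon,
       metrics = list(
         reward_total = sum(bk$reward), reward = bk$reward,
         loss = bk$loss$total, ce = bk$loss$ce, mse = bk$loss$mse,
         theta = thetas, action = actions))
}

#' Fit the attentional search agent
#'
#' The complete training pipeline: (1) supervised pretraining of the
#' feed-forward classifier stack on balanced orbital views (unless a
#' pretrained classifier is supplied), (2) transplant of the pretrained
#' convolutional and FC weights into the full recurrent model, (3)
#' episodic end-to-end Q-learning over the training cubes with a
#' periodically synced target network, (4) per-epoch validation by
#' inference-time search. The best-validation parameters are kept.
#'
#' @param train_cubes,val_cubes lists of [cube_scene()] objects.
#' @param config a [bias3d_config()]; defaults to the `"small"` preset sized
#'   from the data.
#' @param tcfg a [trainer_config()].
#' @param pretrain either `TRUE` (run [pretrain_classifier()] with
#'   `pretrain_args`), `FALSE` (skip), or a pretrained classifier object.
#' @param pretrain_args list of arguments passed on to
#'   [pretrain_classifier()].
#' @param test_threshold confidence threshold used for the validation
#'   searches.
#' @param seed master seed (controls pretraining, initialization and
#'   episode randomness).
#' @param verbose print per-epoch progress.
#' @return an object of class `bias3d`; see [predict.bias3d()],
#'   [summary.bias3d()], [plot.bias3d()].
#' @export
bias3d_fit <- function(train_cubes, val_cubes = list(),
                       config = NULL, tcfg = trainer_config(),
                       pretrain = TRUE, pretrain_args = list(),
                       test_threshold = 0.85, seed = 1L, verbose = FALSE) {
  stopifnot(length(train_cubes) > 0)
  n_classes <- max(vapply(train_cubes, `[[`, integer(1), "target_class")) + 1L
  C <- train_cubes[[1]]$channels
  if (is.null(config))
    config <- bias3d_config(n_classes = n_classes, input_channels = C,
                            preset = "small")
  seeds <- derive_seeds(seed, 4L)
  # 1) pretrain the classifier stack
  pre <- NULL
  if (isTRUE(pretrain)) {
    pre <- do.call(pretrain_classifier,
                   c(list(cubes = train_cubes, config = config,
                          seed = seeds[1]), pretrain_args))
  } else if (inherits(pretrain, "bias3d_pretrain")) pre <- pretrain
  # 2) build + transplant
  model <- bias3d_build(config, seed = seeds[2])
  if (!is.null(pre)) model <- transplant_classifier(model, pre)
  target <- sync_target(model)
  opt <- adam_init(model$params)
  epsilon <- tcfg$epsilon_start
  # per-cube memoised glimpse providers (views are reused across epochs)
  gfs <- lapply(train_cubes, glimpse_provider)
  ep_seeds <- derive_seeds(seeds[3], tcfg$epochs * length(train_cubes))
  curves <- data.frame(epoch = seq_len(tcfg$epochs), mean_reward = NA_real_,
                       mean_loss = NA_real_, val_accuracy = NA_real_,
                       epsilon = NA_real_)
  best <- list(acc = -Inf, params = model$params)
  ep_idx <- 0L
  for (epoch in seq_len(tcfg$epochs)) {
    rew <- numeric(length(train_cubes)); lss <- numeric(length(train_cubes))
    for (ci in seq_along(train_cubes)) {
      ep_idx <- ep_idx + 1L
      res <- train_episode(train_cubes[[ci]], model, target, tcfg,
                           opt = opt, epsilon = epsilon,
                           seed = ep_seeds[ep_idx],
                           glimpse_fn = gfs[[ci]])
      model <- res$model; opt <- res$opt; epsilon <- res$epsilon
      rew[ci] <- res$metrics$reward_total / tcfg$timesteps_per_cube
      lss[ci] <- res$metrics$loss
      if (ep_idx %% tcfg$target_sync_every == 0L) target <- sync_target(model)
    }
    vacc <- NA_real_
    if (length(val_cubes) > 0) {
      ev <- evaluate_cubes(val_cubes, model, threshold = test_threshold,
                           max_steps = tcfg$timesteps_per_cube,
                           jump = tcfg$jump_length, seed = seeds[4] + epoch)
      vacc <- ev$accuracy
      if (vacc >= best$acc) best <- list(acc = vacc, params = model$params)
    } else best <- list(acc = NA_real_, params = model$params)
    curves[epoch, -1] <- c(mean(rew), mean(lss), vacc, epsilon)
    if (verbose)
      message(sprintf("epoch %d: reward %.3f loss %.3f val %.3f eps %.3f",
                      epoch, mean(rew), mean(lss), vacc, epsilon))
  }
  final <- model; final$params <- best$params
  structure(list(model = final, last_model = model, pretrain = pre,
                 config = config, tcfg = tcfg, curves = curves,
                 test_threshold = test_threshold,
                 n_train = length(train_cubes), n_val = length(val_cubes),
                 seed = seed),
            class = "bias3d")
}
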