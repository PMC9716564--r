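# The compiled rollout/BPTT fast path must agree with the pure-R reference
# implementation: same forward outputs, same episode loss, same gradients.

test_that("compiled forward step agrees with the R reference", {
  set.seed(51)
  cfg <- bias3d_config(n_classes = 3, input_channels = 1, preset = "small")
  model <- bias3d_build(cfg, seed = 9)
  st <- reset_state(cfg)
  for (t in 1:4) {  # iterate so recurrent-state handling is covered too
    g <- array(runif(16 * 16 * 3), c(16, 16, 3))
    th <- runif(1, 0, 360)
    oR <- bias3d_forward(model, g, th, st)
    oC <- bias3d:::.cpp_step(model$params, cfg, matrix(g, 256, 3), th, st)
    expect_equal(oR$q_values, as.numeric(oC$q), tolerance = 1e-12)
    expect_equal(oR$class_probs, as.numeric(oC$p), tolerance = 1e-12)
    for (nm in names(st))
      expect_equal(oR$state[[nm]], oC$state[[nm]], tolerance = 1e-12)
    st <- oR$state
  }
})

test_that("compiled episode gradients agree with the R BPTT on a fixed trajectory", {
  set.seed(52)
  cfg <- bias3d_config(n_classes = 3, input_channels = 1, preset = "small",
                       glimpse_size = 8L)
  model <- bias3d_build(cfg, seed = 13)
  target <- bias3d_build(cfg, seed = 14)
  tcfg <- trainer_config(timesteps_per_cube = 6L, jump_length = 30)
  n_grid <- 12L
  gl <- lapply(seq_len(n_grid), function(i) rand_glimpse_mat(cfg))
  labels <- ifelse(abs(((seq_len(n_grid) - 1L) * 30 + 180) %% 360 - 180) <= 45,
                   1L, cfg$n_classes)  # target class 1 near azimuth 0
  actions <- c(1L, 1L, 2L, 3L, 1L, 2L)
  start_idx <- 3L
  T_ <- 6L
  resC <- bias3d:::.cpp_episode(model$params, target$params, cfg, gl, labels,
                                start_idx, 1L, T_, 0, tcfg$gamma,
                                tcfg$lambda_threshold, FALSE,
                                tcfg$bg_ce_weight, actions)
  # R reference: replay the identical trajectory
  st_on <- reset_state(cfg); st_tg <- reset_state(cfg)
  idx <- start_idx
  steps <- vector("list", T_ + 1L)
  for (t in seq_len(T_ + 1L)) {
    gm <- gl[[idx + 1L]]
    on <- bias3d:::model_step(model$params, cfg, gm, idx * 30, st_on)
    tg <- bias3d:::model_step(target$params, cfg, gm, idx * 30, st_tg)
    st_on <- on$state; st_tg <- tg$state
    steps[[t]] <- list(gm = gm, theta = idx * 30, q = on$q, p = on$p,
                       q_target = tg$q, cache = on$cache,
                       label = labels[idx + 1L],
                       action = if (t <= T_) actions[t] else NULL)
    if (t <= T_) {
      a <- actions[t]
      idx <- if (a == 1L) (idx + 1L) %% n_grid
             else if (a == 2L) (idx - 1L + n_grid) %% n_grid else idx
    }
  }
  bkR <- bias3d:::episode_backward(model$params, cfg, steps, tcfg,
                                   bias3d:::onehot(1L, cfg$n_out))
  expect_equal(resC$loss, bkR$loss$total, tolerance = 1e-10)
  expect_equal(as.numeric(resC$reward), bkR$reward, tolerance = 1e-12)
  for (nm in names(bkR$grads))
    expect_equal(resC$grads[[nm]], bkR$grads[[nm]], tolerance = 1e-9,
                 label = nm)
})

test_that("compiled pretraining batch agrees with the R reference", {
  set.seed(8)
  cfg <- bias3d_config(n_classes = 2, input_channels = 1, preset = "small",
                       glimpse_size = 8L)
  pre <- bias3d:::build_pretrain_net(cfg, 5)
  X <- lapply(1:6, function(i) matrix(runif(64 * 3), 64, 3))
  y <- c(0L, 1L, 2L, 0L, 1L, 2L)
  bt <- bias3d:::.cpp_pre_batch(pre$params, cfg, X, y, 1:6)
  acc <- new.env(parent = emptyenv())
  for (nm in names(pre$params)) acc[[nm]] <- 0 * pre$params[[nm]]
  loss <- 0
  for (i in 1:6) {
    f <- bias3d:::pre_fwd(pre$params, cfg, X[[i]])
    bias3d:::pre_bwd(pre$params, cfg, f$cache,
                     bias3d:::onehot(y[i], cfg$n_out), acc, w = 1 / 6)
    loss <- loss - log(f$p[1, y[i] + 1] + 1e-12)
    # prediction parity
    expect_equal(as.numeric(f$p),
                 as.numeric(bias3d:::.cpp_pre_predict(pre$params, cfg, X[i])),
                 tolerance = 1e-12)
  }
  expect_equal(bt$loss, loss, tolerance = 1e-10)
  for (nm in names(pre$params))
    expect_equal(bt$grads[[nm]], acc[[nm]], tolerance = 1e-10, label = nm)
})

test_that("labels in the compiled episode follow the view-label rule", {
  # background (index n) outside +/-45 degrees of the target face
  expect_equal(bias3d:::view_label(46, make_scene(), 3), 3L)
  expect_equal(bias3d:::view_label(45, make_scene(), 3), 0L)
  expect_equal(bias3d:::view_label(315, make_scene(), 3), 0L)
})
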