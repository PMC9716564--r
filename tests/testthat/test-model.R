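# Full-model assembly, recurrent state, and BPTT gradients.

test_that("encode_theta is the sinusoidal pair and 360-periodic", {
  expect_equal(encode_theta(0), c(0, 1))
  expect_equal(encode_theta(90), c(1, 0), tolerance = 1e-12)
  expect_equal(encode_theta(123), encode_theta(123 + 360))
})

test_that("build is seed-deterministic with correct head dimensions", {
  cfg <- tiny_config(n_classes = 3L)
  m1 <- bias3d_build(cfg, seed = 7)
  m2 <- bias3d_build(cfg, seed = 7)
  expect_identical(m1$params, m2$params)
  expect_equal(dim(m1$params$hq_W), c(cfg$fusion, 3L))
  expect_equal(dim(m1$params$hc_W), c(cfg$fusion, 4L))  # n + 1 classes
  m3 <- bias3d_build(cfg, seed = 8)
  expect_false(identical(m1$params, m3$params))
})

test_that("glimpse depth drives the first conv fan-in (grayscale vs RGB)", {
  cfg1 <- bias3d_config(n_classes = 2, input_channels = 1, preset = "small")
  cfg3 <- bias3d_config(n_classes = 2, input_channels = 3, preset = "small")
  expect_equal(cfg1$glimpse_depth, 3L)   # 16 x 16 x 3 glimpse
  expect_equal(cfg3$glimpse_depth, 9L)   # 16 x 16 x 9 glimpse
  m1 <- bias3d_build(cfg1, 1); m3 <- bias3d_build(cfg3, 1)
  expect_equal(nrow(m1$params$clf_c1_W), 9L * 3L)
  expect_equal(nrow(m3$params$clf_c1_W), 9L * 9L)
})

test_that("reset_state: flip-flop maps at one, contexts at zero, idempotent", {
  cfg <- tiny_config()
  st <- reset_state(cfg)
  expect_true(all(st$H_m1 == 1) && all(st$H_m2 == 1) &&
              all(st$H_mf == 1) && all(st$H_pf == 1))
  expect_true(all(st$e_clf == 0) && all(st$j_clf == 0) &&
              all(st$e_mot == 0) && all(st$j_mot == 0) && all(st$e_pos == 0))
  expect_identical(st, reset_state(cfg))
  expect_equal(dim(st$H_m1), c(64L, 2L))  # full-resolution hidden map
  expect_equal(dim(st$H_m2), c(16L, 2L))  # post-pool resolution
})

test_that("forward: valid simplex output, state evolution, determinism", {
  set.seed(21)
  cfg <- tiny_config()
  model <- bias3d_build(cfg, seed = 3)
  g <- array(runif(8 * 8 * 3), c(8, 8, 3))
  st <- reset_state(cfg)
  o1 <- bias3d_forward(model, g, 30, st)
  expect_length(o1$q_values, 3)
  expect_length(o1$class_probs, 3)
  expect_equal(sum(o1$class_probs), 1, tolerance = 1e-6)
  expect_true(all(o1$class_probs >= 0))
  # same glimpse again: the recurrent state has evolved, outputs differ
  o2 <- bias3d_forward(model, g, 30, o1$state)
  expect_false(identical(o1$class_probs, o2$class_probs))
  # Markov in (glimpse, theta, state): bit-identical on replay
  o1b <- bias3d_forward(model, g, 30, reset_state(cfg))
  expect_identical(o1$q_values, o1b$q_values)
  expect_identical(o1$class_probs, o1b$class_probs)
  expect_error(bias3d_forward(model, array(0, c(8, 8, 5)), 0, st), "glimpse")
})

test_that("count_params counts scalars and grows with added layers", {
  expect_equal(count_params(list(W = matrix(0, 4, 3), b = numeric(3))), 15)
  cfg <- tiny_config()
  m <- bias3d_build(cfg, 1)
  n0 <- count_params(m)
  expect_equal(n0, sum(vapply(m$params, length, numeric(1))))
  expect_gt(n0, count_params(m$params[-1]))
  # hand-summed expectation for the tiny architecture
  Cg <- 3; k <- c(2, 2, 2); mker <- c(2, 2)
  expected <-
    (9 * Cg * 2 + 2) + (9 * 2 * 2 + 2) + (9 * 2 * 2 + 2) +      # clf convs
    (2 * 2 * 2 * 4 + 4 * 4 + 3 * 4 + 4) +                       # clf FCEJ
    (2 * (9 * (Cg + 2) * 2) + 4) +                              # motion cff1
    (2 * (9 * (2 + 2) * 2) + 4) +                               # motion cff2
    (2 * 2 * 2 * 4 + 4 * 4 + 3 * 4 + 4) +                       # motion FCEJ
    (2 * (4 + 3) * 3 + 9) +                                     # motion FCJKFF
    (2 * 3 + 3 * 3 + 3) +                                       # position FCE
    (2 * (3 + 2) * 2 + 4) +                                     # position FCJKFF
    ((4 + 3 + 2) * 5 + 5) +                                     # fusion
    (5 * 3 + 3) + (5 * 3 + 3)                                   # heads
  expect_equal(n0, expected)
})

test_that("paper-preset parameter count is of order 10^6", {
  cfg <- bias3d_config(n_classes = 10, input_channels = 1, preset = "paper")
  n <- count_params(bias3d_build(cfg, 1))
  expect_gt(n, 1e6)
  expect_lt(n, 1e7)
  tab <- param_table(bias3d_build(cfg, 1))
  expect_equal(sum(tab$n), n)
  expect_true(all(c("tensor", "shape", "n") %in% names(tab)))
})

test_that("BPTT gradients match central finite differences over an episode", {
  set.seed(31)
  cfg <- tiny_config()
  model <- bias3d_build(cfg, seed = 11)
  pr <- model$params
  # move biases off zero so no relu sits exactly on its kink (all-zero
  # pooled patches + zero bias would make the loss one-sided there)
  for (nm in names(pr))
    if (endsWith(nm, "_b")) pr[[nm]] <- rnorm(length(pr[[nm]]), sd = 0.05)
  tcfg <- trainer_config(gamma = 0.43, timesteps_per_cube = 3L)
  T_ <- 3L
  gms <- lapply(seq_len(T_ + 1L), function(i) rand_glimpse_mat(cfg))
  thetas <- c(10, 22, 34, 46)
  actions <- c(1L, 1L, 3L)
  labels <- c(0L, 1L, 2L)     # includes the background class
  # roll once to fix rewards and bootstrap targets
  st <- reset_state(cfg)
  caches <- vector("list", T_ + 1L)
  steps <- vector("list", T_ + 1L)
  for (t in seq_len(T_ + 1L)) {
    out <- bias3d:::model_step(pr, cfg, gms[[t]], thetas[t], st)
    st <- out$state
    steps[[t]] <- list(gm = gms[[t]], theta = thetas[t], q = out$q,
                       p = out$p, q_target = out$q, cache = out$cache,
                       label = if (t <= T_) labels[t] else 0L,
                       action = if (t <= T_) actions[t] else NULL)
  }
  rew <- vapply(seq_len(T_), function(t)
    compute_reward(as.numeric(steps[[t + 1]]$p), c(1, 0, 0),
                   tcfg$lambda_threshold), numeric(1))
  qnext_max <- vapply(seq_len(T_), function(t)
    max(as.numeric(steps[[t + 1]]$q_target)), numeric(1))
  bk <- bias3d:::episode_backward(pr, cfg, steps, tcfg, c(1, 0, 0))
  # loss value agrees with the from-scratch episode loss
  base <- episode_loss_fn(pr, cfg, gms, thetas, actions, labels,
                          rew, qnext_max, tcfg$gamma)
  expect_equal(bk$loss$total, base, tolerance = 1e-10)
  # spot-check gradients of every tensor by central differences
  h <- 1e-5
  set.seed(77)
  for (nm in names(pr)) {
    idx <- sample(length(pr[[nm]]), min(3, length(pr[[nm]])))
    for (i in idx) {
      prp <- pr; prp[[nm]][i] <- prp[[nm]][i] + h
      prm <- pr; prm[[nm]][i] <- prm[[nm]][i] - h
      num <- (episode_loss_fn(prp, cfg, gms, thetas, actions, labels,
                              rew, qnext_max, tcfg$gamma) -
              episode_loss_fn(prm, cfg, gms, thetas, actions, labels,
                              rew, qnext_max, tcfg$gamma)) / (2 * h)
      expect_equal(bk$grads[[nm]][i], num, tolerance = 1e-4,
                   label = sprintf("d loss / d %s[%d]", nm, i))
    }
  }
})

test_that("gradients reach every trainable tensor (no dead parameters)", {
  set.seed(41)
  cfg <- bias3d_config(n_classes = 3, input_channels = 1, preset = "small",
                       glimpse_size = 8L)
  model <- bias3d_build(cfg, seed = 5)
  tcfg <- trainer_config(timesteps_per_cube = 5L)
  T_ <- 5L
  st <- reset_state(cfg)
  steps <- vector("list", T_ + 1L)
  for (t in seq_len(T_ + 1L)) {
    out <- bias3d:::model_step(model$params, cfg, rand_glimpse_mat(cfg),
                               runif(1, 0, 360), st)
    st <- out$state
    steps[[t]] <- c(out["q"], out["p"], list(q_target = out$q,
                    cache = out$cache, label = sample(0:3, 1),
                    action = if (t <= T_) sample(1:3, 1) else NULL))
  }
  bk <- bias3d:::episode_backward(model$params, cfg, steps, tcfg,
                                  c(1, 0, 0, 0))
  for (nm in names(bk$grads))
    expect_gt(max(abs(bk$grads[[nm]])), 0, label = nm)
})
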