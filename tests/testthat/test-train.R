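# Reward, action selection, TD arithmetic, and episodic training mechanics.

test_that("compute_reward follows the confident-correct rule", {
  expect_equal(compute_reward(c(0.96, 0.02, 0.02), c(1, 0, 0), 0.85), 1)
  expect_equal(compute_reward(c(0.70, 0.20, 0.10), c(1, 0, 0), 0.85), 0)
  expect_equal(compute_reward(c(0.10, 0.90, 0.00), c(1, 0, 0), 0.85), 0)
  expect_error(compute_reward(c(1, 0), c(1, 0, 0), 0.85), "length")
})

test_that("select_action exploits the softmax argmax and explores uniformly", {
  expect_equal(select_action(c(5, 1, 1), epsilon = 0, seed = 1), 1L)
  expect_equal(select_action(c(0, 0, 2), epsilon = 0, seed = 1), 3L)
  # ties broken by lowest index
  expect_equal(select_action(c(2, 2, 0), epsilon = 0, seed = 1), 1L)
  # race persistence: an undecided race repeats the previous response...
  expect_equal(select_action(c(0.1, 0.0, 0.2), epsilon = 0, seed = 1,
                             prev_action = 2L), 2L)
  # ...and a decisive one emits the winner regardless of history
  expect_equal(select_action(c(5, 1, 1), epsilon = 0, seed = 1,
                             prev_action = 2L), 1L)
  # softmax normalization
  expect_equal(sum(softmax(c(3, -1, 2))), 1)
  # epsilon = 1: empirical frequencies near uniform over many draws
  acts <- with(list(), {
    set.seed(7)
    replicate(6000, select_action(c(9, 0, 0), epsilon = 1))
  })
  freq <- tabulate(acts, 3) / 6000
  expect_true(all(abs(freq - 1 / 3) < 0.03))  # ~5 binomial SDs
})

test_that("td_error implements the bootstrap arithmetic", {
  expect_equal(td_error(1, c(2, 1, 0), 1, 0.43), 0.86)
  expect_equal(td_error(0.5, c(1, 3, 2), 0.2, 0), 0.3)   # gamma 0: r - q
  expect_equal(td_error(0, c(0, 0, 0), 0, 0.9), 0)
})

test_that("total_loss adds cross-entropy and TD mean square", {
  # perfect one-hot prediction: zero CE
  l <- total_loss(c(0, 1, 0), c(0, 1, 0), td_errors = 0)
  expect_equal(l$ce, 0, tolerance = 1e-10)
  expect_equal(l$mse, 0)
  # all-zero TDs: mse 0
  l <- total_loss(c(0.5, 0.5), c(1, 0), td_errors = c(0, 0, 0))
  expect_equal(l$mse, 0)
  # total is the sum for random inputs
  set.seed(5)
  P <- t(apply(matrix(runif(12), 3), 1, function(r) r / sum(r)))
  D <- diag(4)[1:3, ]
  td <- rnorm(3)
  l <- total_loss(P, D, td)
  expect_equal(l$total, l$ce + l$mse)
  expect_equal(l$mse, mean(td^2))
})

test_that("sync_target copies parameters and stays stale afterwards", {
  cfg <- tiny_config()
  m <- bias3d_build(cfg, 1)
  tg <- sync_target(m)
  expect_identical(tg$params, m$params)
  m$params$fus_W <- m$params$fus_W + 1
  expect_false(identical(tg$params$fus_W, m$params$fus_W))
})

test_that("train_episode runs 50 steps, bounded integer reward, deterministic", {
  splits <- small_cube_set()
  scn <- splits$train[[1]]
  cfg <- bias3d_config(n_classes = 3, input_channels = 1, preset = "small",
                       glimpse_size = 8L)
  glc <- glimpse_config(window_sizes = c(8, 16, 24), out_size = 8)
  model <- bias3d_build(cfg, seed = 2)
  tcfg <- trainer_config(timesteps_per_cube = 50L, seed = 2)
  gf <- bias3d:::glimpse_provider(scn, glimpse_cfg = glc)
  res <- train_episode(scn, model, sync_target(model), tcfg, seed = 9,
                       glimpse_fn = gf)
  expect_length(res$metrics$action, 50)
  expect_length(res$metrics$reward, 50)
  expect_true(all(res$metrics$reward %in% c(0, 1)))
  expect_gte(res$metrics$reward_total, 0)
  expect_lte(res$metrics$reward_total, 50)
  # same seed, same starting weights: identical trajectory
  res2 <- train_episode(scn, model, sync_target(model), tcfg, seed = 9,
                        glimpse_fn = gf)
  expect_identical(res$metrics$theta, res2$metrics$theta)
  expect_identical(res$metrics$action, res2$metrics$action)
  expect_equal(res$model$params, res2$model$params, tolerance = 1e-12)
  # epsilon decays once per episode with the configured floor
  expect_equal(res$epsilon, max(0.99 * 0.999, 0.1))
  expect_error(train_episode(scn, model, NULL, tcfg), "target_model")
})

test_that("epsilon schedule follows eps0 * decay^k with floor", {
  tcfg <- trainer_config()
  eps <- tcfg$epsilon_start
  for (k in 1:50) eps <- max(eps * tcfg$epsilon_decay, tcfg$epsilon_min)
  expect_equal(eps, max(0.99 * 0.999^50, 0.1))
  lots <- 0.99 * 0.999^(1:5000)
  expect_equal(max(lots[5000], 0.1), 0.1)  # the floor engages eventually
})

test_that("zero learning rate and zero decay leave parameters unchanged", {
  splits <- small_cube_set()
  scn <- splits$train[[1]]
  cfg <- bias3d_config(n_classes = 3, input_channels = 1, preset = "small",
                       glimpse_size = 8L)
  glc <- glimpse_config(window_sizes = c(8, 16, 24), out_size = 8)
  model <- bias3d_build(cfg, seed = 4)
  tcfg <- trainer_config(lr = 0, l2_factor = 0, timesteps_per_cube = 10L)
  gf <- bias3d:::glimpse_provider(scn, glimpse_cfg = glc)
  res <- train_episode(scn, model, sync_target(model), tcfg, seed = 1,
                       glimpse_fn = gf)
  expect_identical(res$model$params, model$params)
})

test_that("with gamma 0 and a perfect classifier the optimal Q is the reward", {
  # 4-state toy orbit solved by value iteration: reward 1 only at state 0;
  # with gamma = 0 the optimal state-action value equals the immediate
  # reward of the landing state.
  n <- 4
  rew_at <- function(s) as.numeric(s == 0)
  move <- function(s, a) switch(a, (s + 1) %% n, (s - 1) %% n, s)
  Q <- matrix(0, n, 3)
  for (it in 1:50) {
    Qn <- Q
    for (s in 0:(n - 1)) for (a in 1:3)
      Qn[s + 1, a] <- rew_at(move(s, a)) + 0 * max(Q[move(s, a) + 1, ])
    if (max(abs(Qn - Q)) < 1e-12) break
    Q <- Qn
  }
  for (s in 0:(n - 1)) for (a in 1:3)
    expect_equal(Q[s + 1, a], rew_at(move(s, a)))
})

test_that("adam with weight decay shrinks weights, not biases", {
  pr <- list(fus_W = matrix(1, 2, 2), fus_b = c(1, 1))
  gr <- list(fus_W = matrix(0, 2, 2), fus_b = c(0, 0))
  opt <- bias3d:::adam_init(pr)
  up <- bias3d:::adam_step(pr, gr, opt, lr = 0.1, weight_decay = 0.5)
  expect_true(all(up$params$fus_W < 1))
  expect_equal(up$params$fus_b, c(1, 1))
})

test_that("gradient clipping preserves direction and caps the global norm", {
  gr <- list(a = matrix(30, 2, 2), b = rep(40, 3))
  cl <- bias3d:::clip_grads(gr, 5)
  nrm <- sqrt(sum(unlist(cl)^2))
  expect_equal(nrm, 5, tolerance = 1e-12)
  expect_equal(cl$a / cl$a[1], gr$a / gr$a[1])
  small <- list(a = matrix(0.1, 2, 2))
  expect_identical(bias3d:::clip_grads(small, 5), small)
})
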