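# Layer primitives against brute-force oracles and closed-form cases.

test_that("conv2d matches identity/constant closed forms", {
  set.seed(1)
  x <- rand_arr(5, 5, 2)
  # centre-tap identity kernel copies channel 1
  W <- array(0, c(3, 3, 2, 1)); W[2, 2, 1, 1] <- 1
  expect_equal(conv2d(x, W)[, , 1], x[, , 1])
  # zero input, bias only
  Wz <- array(0, c(3, 3, 2, 3))
  y <- conv2d(array(0, c(4, 6, 2)), Wz, b = c(0.5, -1, 2))
  expect_equal(y[, , 1], matrix(0.5, 4, 6))
  expect_equal(y[3, 5, ], c(0.5, -1, 2))
})

test_that("conv2d matches the brute-force oracle on random tensors", {
  set.seed(42)
  for (rep in 1:20) {
    h <- sample(3:7, 1); w <- sample(3:7, 1)
    Cin <- sample(1:3, 1); k <- sample(1:4, 1)
    x <- rand_arr(h, w, Cin)
    W <- rand_arr(3, 3, Cin, k)
    b <- rnorm(k)
    expect_equal(conv2d(x, W, b), oracle_conv2d(x, W, b), tolerance = 1e-6)
  }
})

test_that("conv2d rejects channel mismatch", {
  expect_error(conv2d(rand_arr(4, 4, 2), rand_arr(3, 3, 3, 1)), "channels")
})

test_that("relu clamps negatives and is idempotent", {
  expect_identical(relu(-1), 0)
  expect_identical(relu(2), 2)
  x <- rand_arr(4, 4, 2)
  expect_identical(relu(relu(x)), relu(x))
})

test_that("lrn reproduces direct arithmetic and the summation oracle", {
  # single channel, window 1: 2 / (1 + 4) = 0.4
  x1 <- array(2, c(1, 1, 1))
  expect_equal(as.numeric(lrn(x1, k = 1, alpha = 1, beta = 1, c = 1)), 0.4)
  # zero input with k = 1 stays zero
  expect_equal(lrn(array(0, c(3, 3, 2)), k = 1), array(0, c(3, 3, 2)))
  set.seed(7)
  for (rep in 1:20) {
    x <- rand_arr(4, 4, 6)
    expect_equal(lrn(x, k = 2, alpha = 1e-4, beta = 0.75, c = 5),
                 oracle_lrn(x, 2, 1e-4, 0.75, 5), tolerance = 1e-10)
  }
  # default constants (0, 1, 1, C): plain divisive normalization
  x <- rand_arr(3, 3, 4)
  expect_equal(lrn(x), oracle_lrn(x, 0, 1, 1, 4), tolerance = 1e-10)
})

test_that("lrn backward matches finite differences (including k = 0 guard)", {
  set.seed(19)
  for (k in c(0, 1, 2)) {
    X <- matrix(rnorm(24), 8, 3)
    f <- bias3d:::lrn_fwd(X, k, 1, if (k == 2) 0.75 else 1, 3)
    G <- matrix(rnorm(24), 8, 3)
    gX <- bias3d:::lrn_bwd(G, f)
    h <- 1e-6
    num <- 0 * X
    for (i in seq_along(X)) {
      Xp <- X; Xp[i] <- Xp[i] + h
      Xm <- X; Xm[i] <- Xm[i] - h
      num[i] <- (sum(G * bias3d:::lrn_fwd(Xp, k, 1, f$beta, 3)$y) -
                 sum(G * bias3d:::lrn_fwd(Xm, k, 1, f$beta, 3)$y)) / (2 * h)
    }
    expect_equal(gX, num, tolerance = 1e-6)
  }
})

test_that("maxpool matches closed forms and the block oracle", {
  expect_equal(as.numeric(maxpool(array(c(1, 3, 2, 4), c(2, 2, 1)))), 4)
  cst <- array(0.7, c(6, 8, 2))
  expect_equal(maxpool(cst), array(0.7, c(3, 4, 2)))
  expect_equal(dim(maxpool(rand_arr(16, 16, 3))), c(8L, 8L, 3L))
  set.seed(11)
  for (rep in 1:20) {
    x <- rand_arr(2 * sample(1:4, 1), 2 * sample(1:4, 1), sample(1:3, 1))
    expect_equal(maxpool(x), oracle_maxpool(x), tolerance = 1e-12)
  }
  expect_error(maxpool(rand_arr(3, 4, 1)), "even")
})

test_that("fcej_forward reduces correctly and matches the matmul oracle", {
  set.seed(5)
  Wx <- matrix(rnorm(12), 4, 3); We <- matrix(rnorm(9), 3, 3)
  Wj <- matrix(rnorm(6), 2, 3); b <- rnorm(3)
  x <- rnorm(4)
  # zero contexts: plain FC + ReLU
  expect_equal(
    fcej_forward(x, numeric(3), numeric(2), list(Wx = Wx, We = We, Wj = Wj), b),
    pmax(as.numeric(x %*% Wx) + b, 0))
  # all-zero weights: constant relu(b)
  expect_equal(
    fcej_forward(x, rnorm(3), rnorm(2),
                 list(Wx = 0 * Wx, We = 0 * We, Wj = 0 * Wj), b),
    pmax(b, 0))
  for (rep in 1:20) {
    x <- rnorm(4); e <- rnorm(3); j <- rnorm(2)
    expect_equal(fcej_forward(x, e, j, list(Wx = Wx, We = We, Wj = Wj), b),
                 oracle_fcej(x, e, j, Wx, We, Wj, b), tolerance = 1e-6)
  }
  expect_error(fcej_forward(rnorm(5), numeric(3), numeric(2),
                            list(Wx = Wx, We = We, Wj = Wj), b), "shape")
})

test_that("JK flip-flop reproduces the truth table", {
  u <- 3
  # Force gates via huge weights acting on a constant input of 1.
  big <- 50
  gate_w <- function(val) matrix(if (val) big else -big, 1 + u, u)
  Wo <- diag(u)
  h0 <- c(0.2, 0.5, 0.9)
  # hold: J = 0, K = 0 -> H unchanged
  st <- jkff_step(1, h0, gate_w(FALSE), gate_w(FALSE), Wo)
  expect_equal(st$state, h0, tolerance = 1e-10)
  # toggle: J = 1, K = 1 -> 1 - H
  st <- jkff_step(1, h0, gate_w(TRUE), gate_w(TRUE), Wo)
  expect_equal(st$state, 1 - h0, tolerance = 1e-10)
  # set: H_prev = 0 -> H = J
  st <- jkff_step(1, rep(0, u), gate_w(TRUE), gate_w(FALSE), Wo)
  expect_equal(st$state, rep(1, u), tolerance = 1e-10)
  # reset: H_prev = 1, K = 1 -> 0 for any J
  st <- jkff_step(1, rep(1, u), gate_w(FALSE), gate_w(TRUE), Wo)
  expect_equal(st$state, rep(0, u), tolerance = 1e-10)
  # output is tanh of the read-out
  st <- jkff_step(1, h0, gate_w(FALSE), gate_w(FALSE), Wo)
  expect_equal(st$output, tanh(h0), tolerance = 1e-10)
})

test_that("flip-flop state stays in [0,1] over long rollouts", {
  set.seed(3)
  u <- 4; din <- 5
  Wj <- matrix(rnorm((din + u) * u, sd = 2), din + u, u)
  Wk <- matrix(rnorm((din + u) * u, sd = 2), din + u, u)
  Wo <- matrix(rnorm(u * u), u, u)
  H <- rep(1, u)
  for (t in 1:100) {
    st <- jkff_step(rnorm(din, sd = 3), H, Wj, Wk, Wo)
    H <- st$state
    expect_true(all(H >= 0 & H <= 1))
  }
})

test_that("complementary gates collapse the flip-flop to its set gate", {
  # with K = 1 - J the update J(1-H) + (1-K)H = J: the state becomes a
  # pure function of the set gate (a degenerate convex-combination memory)
  set.seed(23)
  u <- 3; din <- 4
  Wj <- matrix(rnorm((din + u) * u), din + u, u)
  H <- runif(u)
  for (rep in 1:5) {
    x <- rnorm(din)
    st <- jkff_step(x, H, Wj, -Wj, diag(u))  # sigmoid(-z) = 1 - sigmoid(z)
    J <- bias3d:::sigmoid(c(x, H) %*% Wj)
    expect_equal(st$state, as.numeric(J), tolerance = 1e-12)
    H <- st$state
  }
})

test_that("flip-flop analytic gradients match finite differences", {
  # Eq-level partials first
  Hp <- matrix(0.3, 1, 1)
  expect_equal(1 - drop(Hp), 0.7)   # dH/dJ = 1 - H_prev
  expect_equal(-drop(Hp), -0.3)     # dH/dK = -H_prev
  set.seed(9)
  din <- 4; u <- 3
  Wj <- matrix(rnorm((din + u) * u), din + u, u)
  Wk <- matrix(rnorm((din + u) * u), din + u, u)
  Wo <- matrix(rnorm(u * u), u, u)
  dev <- jkff_gradcheck(Wj, Wk, Wo, rnorm(din), runif(u))
  expect_lt(dev, 1e-5)
})

test_that("convolutional flip-flop agrees with closed forms", {
  set.seed(13)
  h <- 6; w <- 6; Cin <- 2; k <- 3
  x <- array(runif(h * w * Cin, 0.2, 1), c(h, w, Cin))  # positive input so
  H <- array(runif(h * w * k), c(h, w, k))              # big weights saturate
  # gates forced to ~0: state held
  big <- 60
  Wneg <- array(0, c(3, 3, Cin + k, k)); Wneg[2, 2, , ] <- -big
  ker <- list(Wj = Wneg, Wk = Wneg, Wo = diag(k))
  st <- conv_jkff_step(x, H, ker)
  expect_equal(st$state, H, tolerance = 1e-6)
  # H_prev = 1 (t = 0 init): H_1 = 1 - K
  H1 <- array(1, c(h, w, k))
  Wj <- rand_arr(3, 3, Cin + k, k); Wk <- rand_arr(3, 3, Cin + k, k)
  Wo <- matrix(rnorm(k * k), k, k)
  st <- conv_jkff_step(x, H1, list(Wj = Wj, Wk = Wk, Wo = Wo))
  In <- array(0, c(h, w, Cin + k)); In[, , 1:Cin] <- x; In[, , Cin + 1:k] <- 1
  K <- 1 / (1 + exp(-conv2d(In, Wk)))
  expect_equal(st$state, 1 - K, tolerance = 1e-8)
})

test_that("conv flip-flop with centre-tap kernels equals the sitewise dense oracle", {
  set.seed(17)
  h <- 4; w <- 5; Cin <- 2; k <- 3
  x <- rand_arr(h, w, Cin)
  H <- array(runif(h * w * k), c(h, w, k))
  Wj_d <- matrix(rnorm((Cin + k) * k), Cin + k, k)
  Wk_d <- matrix(rnorm((Cin + k) * k), Cin + k, k)
  Wo <- matrix(rnorm(k * k), k, k)
  Wj_c <- array(0, c(3, 3, Cin + k, k)); Wj_c[2, 2, , ] <- Wj_d
  Wk_c <- array(0, c(3, 3, Cin + k, k)); Wk_c[2, 2, , ] <- Wk_d
  got <- conv_jkff_step(x, H, list(Wj = Wj_c, Wk = Wk_c, Wo = Wo))
  want <- oracle_sitewise_jkff(x, H, Wj_d, Wk_d, Wo)
  expect_equal(got$output, want$output, tolerance = 1e-8)
  expect_equal(got$state, want$state, tolerance = 1e-8)
})

test_that("xavier_init has the prescribed moments and is seed-reproducible", {
  W <- xavier_init(1024, 512, seed = 4)
  v <- var(as.numeric(W))
  expect_lt(abs(v - 2 / 1536) / (2 / 1536), 0.05)
  se <- sqrt(v / length(W))
  expect_lt(abs(mean(W)), 3 * se)
  expect_identical(W, xavier_init(1024, 512, seed = 4))
})
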