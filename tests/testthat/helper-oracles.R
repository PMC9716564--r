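# Brute-force reference implementations used as independent oracles.
# Deliberately written as naive nested loops / direct summation, sharing no
# code with the package's vectorized layer implementations.

oracle_conv2d <- function(x, W, b) {
  h <- dim(x)[1]; w <- dim(x)[2]; Cin <- dim(x)[3]; k <- dim(W)[4]
  y <- array(0, c(h, w, k))
  for (f in 1:k) for (i in 1:h) for (j in 1:w) {
    s <- b[f]
    for (a in 1:3) for (bb in 1:3) for (cc in 1:Cin) {
      ii <- i + a - 2L; jj <- j + bb - 2L
      if (ii >= 1 && ii <= h && jj >= 1 && jj <= w)
        s <- s + x[ii, jj, cc] * W[a, bb, cc, f]
    }
    y[i, j, f] <- s
  }
  y
}

oracle_lrn <- function(x, k, alpha, beta, cw) {
  d <- dim(x); C <- d[3]; half <- cw %/% 2
  y <- array(0, d)
  for (i in 1:d[1]) for (j in 1:d[2]) for (f in 1:C) {
    lo <- max(1, f - half); hi <- min(C, f + half)
    s <- sum(x[i, j, lo:hi]^2)
    den <- (k + alpha * s)^beta
    if (k == 0) den <- den + 1e-8
    y[i, j, f] <- x[i, j, f] / den
  }
  y
}

oracle_maxpool <- function(x) {
  d <- dim(x)
  y <- array(0, c(d[1] / 2, d[2] / 2, d[3]))
  for (f in 1:d[3]) for (i in 1:(d[1] / 2)) for (j in 1:(d[2] / 2))
    y[i, j, f] <- max(x[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j), f])
  y
}

oracle_fcej <- function(x, e, j, Wx, We, Wj, b) {
  a <- as.numeric(x %*% Wx) + as.numeric(e %*% We) + b
  if (!is.null(Wj)) a <- a + as.numeric(j %*% Wj)
  pmax(a, 0)
}

# Dense flip-flop applied independently at every spatial site with shared
# weights; oracle for the convolutional flip-flop when gate kernels have
# support only at the centre tap.
oracle_sitewise_jkff <- function(x, H, Wj_centre, Wk_centre, Wo) {
  d <- dim(x); k <- dim(H)[3]
  O <- array(0, dim(H)); Hn <- array(0, dim(H))
  for (i in 1:d[1]) for (j in 1:d[2]) {
    st <- bias3d::jkff_step(x[i, j, ], H[i, j, ], Wj_centre, Wk_centre, Wo)
    O[i, j, ] <- st$output
    Hn[i, j, ] <- st$state
  }
  list(output = O, state = Hn)
}

rand_arr <- function(...) array(stats::rnorm(prod(c(...))), c(...))
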