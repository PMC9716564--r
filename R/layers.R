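# Network building blocks.
#
# Internally every feature map is a matrix (npix x channels) with the spatial
# extent (h, w) carried alongside; pixel p = i + (j-1)*h (column-major over
# the h x w grid, row i counted from the top of the view). All convolutions
# are 3x3, stride 1, zero same-padding. Each *_fwd returns a cache consumed
# by the matching *_bwd, which is a hand-derived reverse-mode pass (there is
# no autodiff here; correctness is pinned by brute-force oracles and central
# finite differences in the test suite).

# ---- im2col / col2im ------------------------------------------------------

# Precomputed gather/scatter index tables, cached per (h, w, C). The cache
# environment itself stays mutable inside the locked namespace.
.shape_cache <- new.env(parent = emptyenv())

# Gather plan: FWD[p, (ob-1)C+c] is the index into the zero-padded input
# vector (length (h+2)(w+2)C) seen by output pixel p at kernel offset
# ob = dx*3+dy+1, i.e. x[i+dy-1, j+dx-1, c]. INT marks the interior cells
# of the padded vector. BWD[(p,c), ob] indexes into the extended im2col-
# gradient vector (sentinel last position = 0) so that col2im is a plain
# gather + rowSums.
im2col_plan <- function(h, w, C) {
  key <- paste(h, w, C, sep = "_")
  pl <- .shape_cache[[key]]
  if (!is.null(pl)) return(pl)
  hp <- h + 2L; wp <- w + 2L
  npix <- h * w
  ii <- rep(seq_len(h), w); jj <- rep(seq_len(w), each = h)
  FWD <- matrix(0L, npix, 9L * C)
  ob <- 0L
  for (dx in 0:2) for (dy in 0:2) {
    ob <- ob + 1L
    base <- (ii + dy) + (jj + dx - 1L) * hp     # padded (i+dy, j+dx)
    for (c in seq_len(C))
      FWD[, (ob - 1L) * C + c] <- base + (c - 1L) * (hp * wp)
  }
  INT <- as.vector(outer(2:(h + 1L), (2:(w + 1L) - 1L) * hp, "+"))
  INT <- as.vector(outer(INT, (seq_len(C) - 1L) * (hp * wp), "+"))
  sent <- npix * 9L * C + 1L
  BWD <- matrix(sent, npix * C, 9L)
  ob <- 0L
  for (dx in 0:2) for (dy in 0:2) {
    ob <- ob + 1L
    # output pixel that reads input cell (i, j) at this offset
    oi <- ii - (dy - 1L); oj <- jj - (dx - 1L)
    ok <- oi >= 1L & oi <= h & oj >= 1L & oj <= w
    prow <- oi + (oj - 1L) * h
    for (c in seq_len(C)) {
      col <- (ob - 1L) * C + c
      idx <- ifelse(ok, prow + (col - 1L) * npix, sent)
      BWD[(c - 1L) * npix + seq_len(npix), ob] <- idx
    }
  }
  pl <- list(FWD = FWD, INT = INT, BWD = BWD, npad = hp * wp * C,
             npix = npix, C = C)
  .shape_cache[[key]] <- pl
  pl
}

# (npix x C) -> (npix x 9C): column block ob = dx*3+dy+1 holds the input
# shifted by (dy-1, dx-1), so output pixel (i,j) sees x[i+dy-1, j+dx-1, ].
im2col <- function(xm, h, w) {
  pl <- im2col_plan(h, w, ncol(xm))
  xp <- numeric(pl$npad)
  xp[pl$INT] <- xm
  matrix(xp[pl$FWD], pl$npix)
}

# Adjoint of im2col: scatter-add (npix x 9C) back to (npix x C).
col2im <- function(g, h, w) {
  C <- ncol(g) %/% 9L
  pl <- im2col_plan(h, w, C)
  ge <- c(g, 0)
  matrix(rowSums(matrix(ge[pl$BWD], nrow(pl$BWD), 9L)), pl$npix, C)
}

# Kernel array (3,3,Cin,k) <-> flat (9*Cin, k) in im2col column order.
kernel_to_mat <- function(W) {
  d <- dim(W)
  stopifnot(length(d) == 4L, d[1] == 3L, d[2] == 3L)
  Cin <- d[3]; k <- d[4]
  M <- matrix(0, 9L * Cin, k)
  ob <- 0L
  for (dx in 0:2) for (dy in 0:2) {
    ob <- ob + 1L
    M[((ob - 1L) * Cin + 1L):(ob * Cin), ] <- matrix(W[dy + 1L, dx + 1L, , ], Cin, k)
  }
  M
}

mat_to_kernel <- function(M, Cin) {
  k <- ncol(M)
  W <- array(0, c(3L, 3L, Cin, k))
  ob <- 0L
  for (dx in 0:2) for (dy in 0:2) {
    ob <- ob + 1L
    W[dy + 1L, dx + 1L, , ] <- array(M[((ob - 1L) * Cin + 1L):(ob * Cin), ], c(Cin, k))
  }
  W
}

# ---- convolution ----------------------------------------------------------

cv_fwd <- function(xm, h, w, Wm, b = NULL) {
  X2 <- im2col(xm, h, w)
  Y <- X2 %*% Wm
  if (!is.null(b)) Y <- Y + rep(b, each = nrow(Y))
  list(y = Y, X2 = X2)
}

cv_bwd <- function(gY, cache, Wm) {
  list(gx   = col2im(tcrossprod(gY, Wm), cache$h, cache$w),
       dW   = crossprod(cache$X2, gY),
       db   = colSums(gY))
}

#' 2-D convolution (3x3, stride 1, same padding)
#'
#' Correlation-style convolution of a feature map with a bank of 3x3 filters,
#' plus a per-filter bias; spatial dimensions are preserved (zero padding).
#'
#' @param x input feature map, array `h x w x Cin`.
#' @param W filter bank, array `3 x 3 x Cin x k`.
#' @param b bias vector of length `k` (default zeros).
#' @return output feature map, array `h x w x k`.
#' @export
conv2d <- function(x, W, b = NULL) {
  d <- dim(x)
  if (length(d) == 2L) { x <- array(x, c(d, 1L)); d <- dim(x) }
  if (length(d) != 3L) stopf("conv2d: x must be an h x w x C array")
  dw <- dim(W)
  if (length(dw) != 4L || dw[3] != d[3])
    stopf("conv2d: filter channels (%s) do not match input channels (%d)",
          if (length(dw) == 4L) dw[3] else "?", d[3])
  if (is.null(b)) b <- numeric(dw[4])
  h <- d[1]; w <- d[2]
  y <- cv_fwd(matrix(x, h * w, d[3]), h, w, kernel_to_mat(W), b)$y
  array(y, c(h, w, dw[4]))
}

#' Rectified linear activation
#'
#' @param x numeric array.
#' @return `max(0, x)` elementwise, same shape.
#' @export
relu <- function(x) {
  x * (x > 0)
}

# ---- local response normalization ----------------------------------------

# Band matrix for the channel window |f - g| <= floor(c/2); clipping at the
# channel ends falls out of the band structure automatically.
lrn_band <- function(C, cwin) {
  half <- cwin %/% 2L
  f <- seq_len(C)
  outer(f, f, function(a, b) as.numeric(abs(a - b) <= half))
}

lrn_fwd <- function(X, k, alpha, beta, cwin, M = NULL) {
  if (is.null(M)) M <- lrn_band(ncol(X), cwin)
  base <- k + alpha * ((X * X) %*% M)
  D <- if (beta == 1) base else base^beta
  eps <- if (k == 0) 1e-8 else 0
  P <- 1 / (D + eps)
  list(y = X * P, X = X, base = base, P = P, M = M,
       alpha = alpha, beta = beta)
}

lrn_bwd <- function(G, cache) {
  beta <- cache$beta
  base <- cache$base
  P <- cache$P
  Bm1 <- if (beta == 1) (base > 0) + 0
         else ifelse(base > 0, base^(beta - 1), 0)
  Q <- -(cache$alpha * beta) * Bm1 * P * P
  G * P + 2 * cache$X * ((G * cache$X * Q) %*% cache$M)
}

#' Local response normalization across channels
#'
#' Divisive normalization of each activation by a power of the summed squares
#' of its channel neighbourhood at the same pixel, a lateral-inhibition-style
#' rescaling: `N = X / (k + alpha * sum_j X_j^2)^beta`, the sum running over
#' channels `j` within `floor(c/2)` of the normalized channel (clipped at the
#' ends). With `k = 0` a guard of `1e-8` is added to the denominator.
#'
#' @param x feature map, array `h x w x C` (or a matrix treated as `C = 1`).
#' @param k,alpha,beta scalar constants (defaults `0, 1, 1`: plain divisive
#'   normalization by the summed square).
#' @param c channel neighbourhood length; default the full channel count.
#' @return normalized array, same shape as `x`.
#' @export
lrn <- function(x, k = 0, alpha = 1, beta = 1, c = NULL) {
  d <- dim(x)
  if (is.null(d) || length(d) == 2L) {
    d <- c(if (is.null(d)) c(length(x), 1L) else d, 1L)
    x <- array(x, d)
  }
  if (!is.null(c) && c < 1) stopf("lrn: c must be >= 1")
  if (is.null(c)) c <- d[3]
  y <- lrn_fwd(matrix(x, d[1] * d[2], d[3]), k, alpha, beta, c)$y
  array(y, d)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- max pooling ----------------------------------------------------------

mp_plan <- function(h, w) {
  key <- paste("mp", h, w, sep = "_")
  pl <- .shape_cache[[key]]
  if (!is.null(pl)) return(pl)
  base <- as.vector(outer(seq(1L, h, 2L), (seq(1L, w, 2L) - 1L) * h, "+"))
  idx4 <- cbind(base, base + 1L, base + h, base + h + 1L)
  pl <- list(idx4 = idx4, rows4 = as.vector(idx4), n2 = length(base))
  .shape_cache[[key]] <- pl
  pl
}

mp_fwd <- function(X, h, w) {
  if (h %% 2L || w %% 2L) stopf("maxpool: spatial dims must be even, got %d x %d", h, w)
  pl <- mp_plan(h, w)
  n2 <- pl$n2
  G <- X[pl$rows4, , drop = FALSE]           # the four corners, stacked
  i1 <- seq_len(n2)
  y <- pmax(pmax(G[i1, , drop = FALSE], G[n2 + i1, , drop = FALSE]),
            pmax(G[2L * n2 + i1, , drop = FALSE], G[3L * n2 + i1, , drop = FALSE]))
  # argmax is only needed by the backward pass; computed lazily there
  list(y = y, G = G, n2 = n2, idx4 = pl$idx4, h = h, w = w, C = ncol(X))
}

mp_bwd <- function(Gr, cache) {
  n2 <- cache$n2; C <- cache$C
  i1 <- seq_len(n2)
  G <- cache$G
  mm <- cbind(as.vector(G[i1, , drop = FALSE]),
              as.vector(G[n2 + i1, , drop = FALSE]),
              as.vector(G[2L * n2 + i1, , drop = FALSE]),
              as.vector(G[3L * n2 + i1, , drop = FALSE]))
  amax <- max.col(mm, ties.method = "first")   # first corner wins ties
  p <- rep.int(i1, C)
  ch <- rep(seq_len(C), each = n2)
  rows <- cache$idx4[cbind(p, amax)]
  gX <- matrix(0, cache$h * cache$w, C)
  gX[rows + (ch - 1L) * (cache$h * cache$w)] <- as.vector(Gr)
  gX
}

#' 2x2 max pooling with stride 2
#'
#' @param x feature map, array `h x w x C` with even `h` and `w`.
#' @return array `h/2 x w/2 x C`; each entry the maximum of its 2x2 block.
#' @export
maxpool <- function(x) {
  d <- dim(x)
  if (length(d) == 2L) { x <- array(x, c(d, 1L)); d <- dim(x) }
  y <- mp_fwd(matrix(x, d[1] * d[2], d[3]), d[1], d[2])$y
  array(y, c(d[1] %/% 2L, d[2] %/% 2L, d[3]))
}

# ---- fully connected Elman-Jordan layer -----------------------------------

# Wfull optionally carries rbind(Wx, We[, Wj]) so the three context
# products collapse into one matmul.
fcej_fwd <- function(x, elman, jordan, Wx, We, Wj, b, Wfull = NULL) {
  if (!is.null(Wfull)) {
    In <- if (is.null(Wj)) cbind(x, elman) else cbind(x, elman, jordan)
    a <- In %*% Wfull + b
  } else {
    a <- x %*% Wx + elman %*% We + b
    if (!is.null(Wj)) a <- a + jordan %*% Wj
  }
  list(y = relu(a), a = a, x = x, elman = elman, jordan = jordan)
}

# Returns grads for the three inputs and the parameters.
fcej_bwd <- function(G, cache, Wx, We, Wj) {
  ga <- G * (cache$a > 0)
  out <- list(gx = tcrossprod(ga, Wx), ge = tcrossprod(ga, We),
              dWx = crossprod(cache$x, ga), dWe = crossprod(cache$elman, ga),
              db = colSums(ga))
  if (!is.null(Wj)) {
    out$gj <- tcrossprod(ga, Wj)
    out$dWj <- crossprod(cache$jordan, ga)
  }
  out
}

#' Fully connected layer with Elman and Jordan context inputs
#'
#' One step of the recurrent fully connected layer: a ReLU of the sum of
#' three affine maps - the feed-forward input, the layer's own previous
#' output (Elman context) and the pipeline's previous final output (Jordan
#' context). Contexts are read-only here; the caller stores the returned
#' activation (and the pipeline head output) for the next step.
#'
#' @param x_t feed-forward input vector at time t.
#' @param elman previous output of this layer (zeros at episode start).
#' @param jordan previous pipeline head output; may be `NULL` for an
#'   Elman-only layer (then `weights$Wj` must also be `NULL`).
#' @param weights list with matrices `Wx` (`d_in x d`), `We` (`d x d`) and
#'   optionally `Wj` (`d_jordan x d`).
#' @param bias bias vector of length `d`.
#' @return activation vector of length `d`.
#' @export
fcej_forward <- function(x_t, elman, jordan, weights, bias) {
  x <- matrix(as.numeric(x_t), 1L)
  e <- matrix(as.numeric(elman), 1L)
  if (ncol(x) != nrow(weights$Wx) || ncol(e) != nrow(weights$We))
    stopf("fcej_forward: input/context shapes do not match weights")
  j <- if (!is.null(weights$Wj)) {
    if (is.null(jordan)) stopf("fcej_forward: Wj given but jordan context is NULL")
    matrix(as.numeric(jordan), 1L)
  } else NULL
  drop(fcej_fwd(x, e, j, weights$Wx, weights$We, weights$Wj, bias)$y)
}

# ---- JK flip-flop layers --------------------------------------------------

# Dense flip-flop step on row-vector input (1 x d_in) and state (1 x u).
# The two gate products share one matmul against cbind(Wj, Wk).
jkff_fwd <- function(x, H, Wj, Wk, Wo, Wjk = NULL) {
  In <- cbind(x, H)
  u <- ncol(H)
  JK <- sigmoid(In %*% (Wjk %||% cbind(Wj, Wk)))
  J <- JK[, seq_len(u), drop = FALSE]
  K <- JK[, u + seq_len(u), drop = FALSE]
  Hn <- J * (1 - H) + (1 - K) * H
  O <- tanh(Hn %*% Wo)
  list(O = O, Hn = Hn, In = In, J = J, K = K, H = H, O2 = O * O)
}

# gO: grad wrt output; gHn_extra: grad wrt H_t arriving from step t+1.
# Returns parameter grads, grad wrt x, and grad wrt H_{t-1}.
jkff_bwd <- function(gO, gHn_extra, cache, Wj, Wk, Wo) {
  with(cache, {
    gZo <- gO * (1 - O2)
    gHn <- tcrossprod(gZo, Wo)
    if (!is.null(gHn_extra)) gHn <- gHn + gHn_extra
    dWo <- crossprod(Hn, gZo)
    gJ <- gHn * (1 - H)          # dH_t/dJ = 1 - H_{t-1}
    gK <- gHn * (-H)             # dH_t/dK = -H_{t-1}
    zJ <- gJ * J * (1 - J)
    zK <- gK * K * (1 - K)
    dWj <- crossprod(In, zJ)
    dWk <- crossprod(In, zK)
    gIn <- tcrossprod(zJ, Wj) + tcrossprod(zK, Wk)
    dx <- ncol(In) - ncol(H)
    gx <- gIn[, seq_len(dx), drop = FALSE]
    gH <- gIn[, dx + seq_len(ncol(H)), drop = FALSE] + gHn * (1 - K - J)
    list(dWj = dWj, dWk = dWk, dWo = dWo, gx = gx, gH = gH)
  })
}

#' One step of a dense JK flip-flop layer
#'
#' The layer's bounded hidden state is updated by two sigmoid gates acting as
#' the J (set) and K (reset) inputs of a JK flip-flop:
#' `H_t = J * (1 - H_prev) + (1 - K) * H_prev`, with
#' `J = sigmoid(In %*% W_j)`, `K = sigmoid(In %*% W_k)` and
#' `In = c(x_t, H_prev)`. The emitted output is `tanh(H_t %*% W_out)`.
#' There are no bias terms. `H_prev` is initialised to ones at time 0.
#'
#' @param x_t input vector.
#' @param state hidden state vector `H_prev`, entries in `[0, 1]`.
#' @param W_j,W_k gate weight matrices, `(d_in + u) x u`.
#' @param W_out output weight matrix, `u x u_out`.
#' @return list with `output` (tanh read-out) and `state` (the new `H_t`).
#' @export
jkff_step <- function(x_t, state, W_j, W_k, W_out) {
  x <- matrix(as.numeric(x_t), 1L)
  H <- matrix(as.numeric(state), 1L)
  if (ncol(x) + ncol(H) != nrow(W_j) || nrow(W_k) != nrow(W_j))
    stopf("jkff_step: gate weight shape does not match input + state")
  f <- jkff_fwd(x, H, W_j, W_k, W_out)
  list(output = drop(f$O), state = drop(f$Hn))
}

# Convolutional flip-flop step. x: (npix x Cin), H: (npix x k).
# Gates are 3x3 same-padded convolutions over the channel concatenation
# [x; H]; the read-out is a 1x1 convolution (channel mixing) of H_t.
cjkff_fwd <- function(x, H, h, w, Wj, Wk, Wo, Wjk = NULL) {
  In2 <- im2col(cbind(x, H), h, w)
  u <- ncol(H)
  JK <- sigmoid(In2 %*% (Wjk %||% cbind(Wj, Wk)))
  J <- JK[, seq_len(u), drop = FALSE]
  K <- JK[, u + seq_len(u), drop = FALSE]
  Hn <- J * (1 - H) + (1 - K) * H
  O <- tanh(Hn %*% Wo)
  list(O = O, Hn = Hn, In2 = In2, J = J, K = K, H = H, O2 = O * O,
       h = h, w = w)
}

cjkff_bwd <- function(gO, gHn_extra, cache, Wj, Wk, Wo) {
  with(cache, {
    gZo <- gO * (1 - O2)
    gHn <- tcrossprod(gZo, Wo)
    if (!is.null(gHn_extra)) gHn <- gHn + gHn_extra
    dWo <- crossprod(Hn, gZo)
    gJ <- gHn * (1 - H)
    gK <- gHn * (-H)
    zJ <- gJ * J * (1 - J)
    zK <- gK * K * (1 - K)
    dWj <- crossprod(In2, zJ)
    dWk <- crossprod(In2, zK)
    gIn <- col2im(tcrossprod(zJ, Wj) + tcrossprod(zK, Wk), h, w)
    Cin <- ncol(gIn) - ncol(H)
    list(dWj = dWj, dWk = dWk, dWo = dWo,
         gx = gIn[, seq_len(Cin), drop = FALSE],
         gH = gIn[, Cin + seq_len(ncol(H)), drop = FALSE] + gHn * (1 - K - J))
  })
}

#' One step of a convolutional JK flip-flop layer
#'
#' Convolutional variant of [jkff_step()]: the J and K gates are 3x3
#' same-padded convolutions over the channel concatenation of the input map
#' and the hidden map, sigmoid-squashed; the flip-flop update is applied
#' elementwise; the output is the tanh of a 1x1 convolution of the new
#' hidden map. No biases.
#'
#' @param x_t input feature map, array `h x w x Cin`.
#' @param state hidden map `H_prev`, array `h x w x k`.
#' @param kernels list with `Wj`, `Wk` (arrays `3 x 3 x (Cin+k) x k`) and
#'   `Wo` (matrix `k x k`, the 1x1 read-out).
#' @return list with `output` (`h x w x k` array) and `state` (new hidden map).
#' @export
conv_jkff_step <- function(x_t, state, kernels) {
  d <- dim(x_t); dh <- dim(state)
  if (length(d) != 3L || length(dh) != 3L || any(d[1:2] != dh[1:2]))
    stopf("conv_jkff_step: input and state maps must share spatial dims")
  k <- dh[3]
  Wj <- if (is.matrix(kernels$Wj)) kernels$Wj else kernel_to_mat(kernels$Wj)
  Wk <- if (is.matrix(kernels$Wk)) kernels$Wk else kernel_to_mat(kernels$Wk)
  if (nrow(Wj) != 9L * (d[3] + k))
    stopf("conv_jkff_step: gate kernels do not match input + state channels")
  f <- cjkff_fwd(matrix(x_t, d[1] * d[2], d[3]), matrix(state, d[1] * d[2], k),
                 d[1], d[2], Wj, Wk, kernels$Wo)
  list(output = array(f$O, c(d[1], d[2], k)),
       state  = array(f$Hn, c(d[1], d[2], k)))
}

# ---- initialization -------------------------------------------------------

#' Xavier (Glorot) normal initialization
#'
#' Draws an `m_in x m_out` weight matrix i.i.d. from a zero-mean normal with
#' variance `2 / (m_in + m_out)`, which keeps activation variance roughly
#' constant across layers.
#'
#' @param m_in,m_out fan-in and fan-out (positive integers).
#' @param seed optional integer seed (the ambient RNG state is restored).
#' @return matrix `m_in x m_out`.
#' @export
xavier_init <- function(m_in, m_out, seed = NULL) {
  stopifnot(m_in >= 1, m_out >= 1)
  with_seed(seed, matrix(stats::rnorm(m_in * m_out, 0, sqrt(2 / (m_in + m_out))),
                         m_in, m_out))
}

#' Finite-difference check of the flip-flop gradients
#'
#' Verifies the hand-derived backward pass of a dense JK flip-flop layer:
#' the analytic gradients of the scalar loss `sum(O_t) + sum(H_t)` with
#' respect to `W_j`, `W_k`, `W_out`, the input and the previous state are
#' compared against central finite differences.
#'
#' @param W_j,W_k,W_out layer weights as in [jkff_step()].
#' @param x input vector.
#' @param H_prev previous hidden state vector in `[0, 1]`.
#' @param h finite-difference step (default `1e-6`).
#' @return maximum absolute relative deviation across all checked parameters.
#' @export
jkff_gradcheck <- function(W_j, W_k, W_out, x, H_prev, h = 1e-6) {
  x <- matrix(as.numeric(x), 1L); H <- matrix(as.numeric(H_prev), 1L)
  loss <- function(Wj, Wk, Wo, xx, HH) {
    f <- jkff_fwd(xx, HH, Wj, Wk, Wo)
    sum(f$O) + sum(f$Hn)
  }
  f <- jkff_fwd(x, H, W_j, W_k, W_out)
  g <- jkff_bwd(gO = matrix(1, 1L, ncol(f$O)),
                gHn_extra = matrix(1, 1L, ncol(f$Hn)),
                cache = f, Wj = W_j, Wk = W_k, Wo = W_out)
  maxdev <- 0
  fd_block <- function(W, dW, setter) {
    for (i in seq_along(W)) {
      Wp <- W; Wp[i] <- Wp[i] + h
      Wm <- W; Wm[i] <- Wm[i] - h
      num <- (setter(Wp) - setter(Wm)) / (2 * h)
      dev <- abs(num - dW[i]) / max(1, abs(num))
      maxdev <<- max(maxdev, dev)
    }
  }
  fd_block(W_j, g$dWj, function(W) loss(W, W_k, W_out, x, H))
  fd_block(W_k, g$dWk, function(W) loss(W_j, W, W_out, x, H))
  fd_block(W_out, g$dWo, function(W) loss(W_j, W_k, W, x, H))
  fd_block(x, g$gx, function(W) loss(W_j, W_k, W_out, W, H))
  fd_block(H, g$gH, function(W) loss(W_j, W_k, W_out, x, W))
  maxdev
}
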