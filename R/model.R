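# The dual-pathway agent: a classifier ("what") pipeline, a camera-motion
# ("where") pipeline built on convolutional and dense JK flip-flop layers,
# and a camera-position pipeline feeding the azimuth into the high-level
# features. The three pipeline outputs are concatenated, fused by one FC
# layer, and read out by a linear Q-value head (3 actions) and a softmax
# classification head (n target classes + background).
#
# Recurrence wiring per step t -> t+1:
#   * Elman contexts: each first FC layer receives its own previous output.
#   * Jordan contexts: the classifier FC layer receives the previous softmax
#     output; the motion FC layer receives the previous Q-values; the
#     position pipeline is Elman-only.
#   * Flip-flop hidden maps H (init ones) evolve by the JK update.

#' Model configuration
#'
#' Widths of every layer of the three pipelines. The `"paper"` preset keeps
#' the published architecture (conv kernels 16/32/64, FC widths 512, position
#' 128/64); the `"small"` preset scales all widths down for CPU-budget
#' experiments while preserving the architecture exactly.
#'
#' @param n_classes number of target classes `n` (the softmax head has
#'   `n + 1` outputs including the background class).
#' @param input_channels channels `C` of the camera view (1 grayscale,
#'   3 RGB); the glimpse depth is `n_windows * C`.
#' @param preset `"paper"` or `"small"`.
#' @param glimpse_size,n_windows glimpse geometry (16 px, 3 windows).
#' @param clf_conv,clf_fc classifier pipeline widths.
#' @param mot_conv,mot_fc,mot_ff camera-motion pipeline widths.
#' @param pos_fc,pos_ff camera-position pipeline widths.
#' @param fusion width of the post-concatenation FC layer.
#' @param lrn_k,lrn_alpha,lrn_beta response-normalization constants (the
#'   neighbourhood length is the full channel count of each layer).
#' @return object of class `bias3d_config`.
#' @export
bias3d_config <- function(n_classes, input_channels = 1L,
                          preset = c("paper", "small"),
                          glimpse_size = 16L, n_windows = 3L,
                          clf_conv = NULL, clf_fc = NULL,
                          mot_conv = NULL, mot_fc = NULL, mot_ff = NULL,
                          pos_fc = NULL, pos_ff = NULL, fusion = NULL,
                          lrn_k = 0, lrn_alpha = 1, lrn_beta = 1) {
  preset <- match.arg(preset)
  if (n_classes < 2) stopf("bias3d_config: need at least 2 classes")
  def <- if (preset == "paper") {
    list(clf_conv = c(16L, 32L, 64L), clf_fc = 512L,
         mot_conv = c(16L, 32L), mot_fc = 512L, mot_ff = 512L,
         pos_fc = 128L, pos_ff = 64L, fusion = 512L)
  } else {
    list(clf_conv = c(12L, 24L, 32L), clf_fc = 64L,
         mot_conv = c(8L, 16L), mot_fc = 64L, mot_ff = 64L,
         pos_fc = 32L, pos_ff = 16L, fusion = 128L)
  }
  cfg <- list(n_classes = as.integer(n_classes),
              input_channels = as.integer(input_channels),
              glimpse_size = as.integer(glimpse_size),
              n_windows = as.integer(n_windows),
              clf_conv = clf_conv %||% def$clf_conv,
              clf_fc = clf_fc %||% def$clf_fc,
              mot_conv = mot_conv %||% def$mot_conv,
              mot_fc = mot_fc %||% def$mot_fc,
              mot_ff = mot_ff %||% def$mot_ff,
              pos_fc = pos_fc %||% def$pos_fc,
              pos_ff = pos_ff %||% def$pos_ff,
              fusion = fusion %||% def$fusion,
              lrn_k = lrn_k, lrn_alpha = lrn_alpha, lrn_beta = lrn_beta,
              preset = preset)
  if (any(unlist(cfg[c("clf_conv", "clf_fc", "mot_conv", "mot_fc", "mot_ff",
                       "pos_fc", "pos_ff", "fusion")]) < 1))
    stopf("bias3d_config: all widths must be positive")
  if (cfg$glimpse_size %% 4L != 0L)
    stopf("bias3d_config: glimpse_size must be divisible by 4 (two poolings)")
  cfg$glimpse_depth <- cfg$n_windows * cfg$input_channels
  g <- cfg$glimpse_size
  cfg$flat_clf <- (g %/% 4L)^2 * cfg$clf_conv[3]
  cfg$flat_mot <- (g %/% 4L)^2 * cfg$mot_conv[2]
  cfg$concat <- cfg$clf_fc + cfg$mot_ff + cfg$pos_ff
  cfg$n_out <- cfg$n_classes + 1L
  # precomputed LRN channel-band matrices, one per normalized layer width
  cfg$bands <- lapply(stats::setNames(nm = unique(c(cfg$clf_conv[1:2], cfg$mot_conv))),
                      function(C) lrn_band(as.integer(C), as.integer(C)))
  structure(cfg, class = "bias3d_config")
}

#' Sinusoidal encoding of the camera azimuth
#'
#' @param theta azimuth in degrees.
#' @return `c(sin(theta), cos(theta))` (theta converted to radians); periodic
#'   in 360 degrees.
#' @export
encode_theta <- function(theta) {
  th <- wrap_theta(theta) * pi / 180
  c(sin(th), cos(th))
}

#' Build the network with Xavier-initialized weights
#'
#' @param cfg a [bias3d_config()].
#' @param seed integer seed; the same seed reproduces the same parameters.
#' @return object of class `bias3d_net` (list with `params` and `config`).
#' @export
bias3d_build <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "bias3d_config"))
  Cg <- cfg$glimpse_depth
  k1 <- cfg$clf_conv[1]; k2 <- cfg$clf_conv[2]; k3 <- cfg$clf_conv[3]
  m1 <- cfg$mot_conv[1]; m2 <- cfg$mot_conv[2]
  FC <- cfg$clf_fc; M <- cfg$mot_fc; FF <- cfg$mot_ff
  P <- cfg$pos_fc; PF <- cfg$pos_ff; U <- cfg$fusion
  pr <- with_seed(seed, {
    xv <- function(a, b) xavier_init(a, b)
    list(
      clf_c1_W = xv(9L * Cg, k1), clf_c1_b = numeric(k1),
      clf_c2_W = xv(9L * k1, k2), clf_c2_b = numeric(k2),
      clf_c3_W = xv(9L * k2, k3), clf_c3_b = numeric(k3),
      clf_fc_Wx = xv(cfg$flat_clf, FC), clf_fc_We = xv(FC, FC),
      clf_fc_Wj = xv(cfg$n_out, FC), clf_fc_b = numeric(FC),
      mot_f1_Wj = xv(9L * (Cg + m1), m1), mot_f1_Wk = xv(9L * (Cg + m1), m1),
      mot_f1_Wo = xv(m1, m1),
      mot_f2_Wj = xv(9L * (m1 + m2), m2), mot_f2_Wk = xv(9L * (m1 + m2), m2),
      mot_f2_Wo = xv(m2, m2),
      mot_fc_Wx = xv(cfg$flat_mot, M), mot_fc_We = xv(M, M),
      mot_fc_Wj = xv(3L, M), mot_fc_b = numeric(M),
      mot_ff_Wj = xv(M + FF, FF), mot_ff_Wk = xv(M + FF, FF),
      mot_ff_Wo = xv(FF, FF),
      pos_fc_Wx = xv(2L, P), pos_fc_We = xv(P, P), pos_fc_b = numeric(P),
      pos_ff_Wj = xv(P + PF, PF), pos_ff_Wk = xv(P + PF, PF),
      pos_ff_Wo = xv(PF, PF),
      fus_W = xv(cfg$concat, U), fus_b = numeric(U),
      hq_W = xv(U, 3L), hq_b = numeric(3L),
      hc_W = xv(U, cfg$n_out), hc_b = numeric(cfg$n_out))
  })
  structure(list(params = pr, config = cfg), class = "bias3d_net")
}

#' Initial recurrent state
#'
#' Flip-flop hidden maps start at ones; Elman and Jordan contexts at zeros.
#'
#' @param cfg a [bias3d_config()].
#' @return object of class `bias3d_state`.
#' @export
reset_state <- function(cfg) {
  g <- cfg$glimpse_size
  structure(list(
    e_clf = matrix(0, 1, cfg$clf_fc), j_clf = matrix(0, 1, cfg$n_out),
    e_mot = matrix(0, 1, cfg$mot_fc), j_mot = matrix(0, 1, 3),
    e_pos = matrix(0, 1, cfg$pos_fc),
    H_m1 = matrix(1, g * g, cfg$mot_conv[1]),
    H_m2 = matrix(1, (g %/% 2L)^2, cfg$mot_conv[2]),
    H_mf = matrix(1, 1, cfg$mot_ff),
    H_pf = matrix(1, 1, cfg$pos_ff)), class = "bias3d_state")
}

# Zero-valued carry used to seed the backward recursion at the last step.
zero_carry <- function(cfg) {
  st <- reset_state(cfg)
  lapply(unclass(st), function(x) 0 * x)
}

# ---- forward step ---------------------------------------------------------

# Precombined weight views (gate pairs, stacked context weights, joined
# heads) so the forward pass spends fewer, larger BLAS calls. Rebuilt after
# every parameter update (adam steps once per episode).
make_aux <- function(pr) {
  list(f1_Wjk = cbind(pr$mot_f1_Wj, pr$mot_f1_Wk),
       f2_Wjk = cbind(pr$mot_f2_Wj, pr$mot_f2_Wk),
       mff_Wjk = cbind(pr$mot_ff_Wj, pr$mot_ff_Wk),
       pff_Wjk = cbind(pr$pos_ff_Wj, pr$pos_ff_Wk),
       clf_fc_W = rbind(pr$clf_fc_Wx, pr$clf_fc_We, pr$clf_fc_Wj),
       mot_fc_W = rbind(pr$mot_fc_Wx, pr$mot_fc_We, pr$mot_fc_Wj),
       pos_fc_W = rbind(pr$pos_fc_Wx, pr$pos_fc_We),
       head_W = cbind(pr$hq_W, pr$hc_W),
       head_b = c(pr$hq_b, pr$hc_b))
}

# gm: glimpse as (g*g x depth) matrix. Returns q (1x3), p (1 x n+1),
# the updated state, and the cache for the backward pass.
model_step <- function(pr, cfg, gm, theta, st, aux = NULL) {
  if (is.null(aux)) aux <- make_aux(pr)
  g <- cfg$glimpse_size; g2 <- g %/% 2L
  lk <- cfg$lrn_k; la <- cfg$lrn_alpha; lb <- cfg$lrn_beta
  band <- function(C) cfg$bands[[as.character(C)]]
  # classifier pipeline
  c1 <- cv_fwd(gm, g, g, pr$clf_c1_W, pr$clf_c1_b); c1$h <- g; c1$w <- g
  l1 <- lrn_fwd(c1$y, lk, la, lb, NA, M = band(cfg$clf_conv[1]))
  r1 <- relu(l1$y)
  p1 <- mp_fwd(r1, g, g)
  c2 <- cv_fwd(p1$y, g2, g2, pr$clf_c2_W, pr$clf_c2_b); c2$h <- g2; c2$w <- g2
  l2 <- lrn_fwd(c2$y, lk, la, lb, NA, M = band(cfg$clf_conv[2]))
  r2 <- relu(l2$y)
  p2 <- mp_fwd(r2, g2, g2)
  c3 <- cv_fwd(p2$y, g2 %/% 2L, g2 %/% 2L, pr$clf_c3_W, pr$clf_c3_b)
  c3$h <- g2 %/% 2L; c3$w <- g2 %/% 2L
  r3 <- relu(c3$y)
  flat_c <- matrix(r3, 1L)
  fc_c <- fcej_fwd(flat_c, st$e_clf, st$j_clf,
                   pr$clf_fc_Wx, pr$clf_fc_We, pr$clf_fc_Wj, pr$clf_fc_b,
                   Wfull = aux$clf_fc_W)
  # camera-motion pipeline
  f1 <- cjkff_fwd(gm, st$H_m1, g, g, pr$mot_f1_Wj, pr$mot_f1_Wk,
                  pr$mot_f1_Wo, Wjk = aux$f1_Wjk)
  ml1 <- lrn_fwd(f1$O, lk, la, lb, NA, M = band(cfg$mot_conv[1]))
  mr1 <- relu(ml1$y)
  mp1 <- mp_fwd(mr1, g, g)
  f2 <- cjkff_fwd(mp1$y, st$H_m2, g2, g2, pr$mot_f2_Wj, pr$mot_f2_Wk,
                  pr$mot_f2_Wo, Wjk = aux$f2_Wjk)
  ml2 <- lrn_fwd(f2$O, lk, la, lb, NA, M = band(cfg$mot_conv[2]))
  mr2 <- relu(ml2$y)
  mp2 <- mp_fwd(mr2, g2, g2)
  flat_m <- matrix(mp2$y, 1L)
  fc_m <- fcej_fwd(flat_m, st$e_mot, st$j_mot,
                   pr$mot_fc_Wx, pr$mot_fc_We, pr$mot_fc_Wj, pr$mot_fc_b,
                   Wfull = aux$mot_fc_W)
  ff_m <- jkff_fwd(fc_m$y, st$H_mf, pr$mot_ff_Wj, pr$mot_ff_Wk,
                   pr$mot_ff_Wo, Wjk = aux$mff_Wjk)
  # camera-position pipeline
  enc <- matrix(encode_theta(theta), 1L)
  fc_p <- fcej_fwd(enc, st$e_pos, NULL, pr$pos_fc_Wx, pr$pos_fc_We, NULL,
                   pr$pos_fc_b, Wfull = aux$pos_fc_W)
  ff_p <- jkff_fwd(fc_p$y, st$H_pf, pr$pos_ff_Wj, pr$pos_ff_Wk,
                   pr$pos_ff_Wo, Wjk = aux$pff_Wjk)
  # fusion + heads
  cat_ <- cbind(fc_c$y, ff_m$O, ff_p$O)
  fa <- cat_ %*% pr$fus_W + rep(pr$fus_b, each = 1L)
  fy <- relu(fa)
  qz <- fy %*% aux$head_W + aux$head_b
  q <- qz[, 1:3, drop = FALSE]
  z <- qz[, -(1:3), drop = FALSE]
  p <- matrix(softmax(z), 1L)
  state <- structure(list(
    e_clf = fc_c$y, j_clf = p, e_mot = fc_m$y, j_mot = q, e_pos = fc_p$y,
    H_m1 = f1$Hn, H_m2 = f2$Hn, H_mf = ff_m$Hn, H_pf = ff_p$Hn),
    class = "bias3d_state")
  cache <- list(c1 = c1, l1 = l1, r1 = r1, p1 = p1, c2 = c2, l2 = l2,
                r2 = r2, p2 = p2, c3 = c3, r3 = r3, fc_c = fc_c,
                f1 = f1, ml1 = ml1, mr1 = mr1, mp1 = mp1, f2 = f2,
                ml2 = ml2, mr2 = mr2, mp2 = mp2, fc_m = fc_m, ff_m = ff_m,
                fc_p = fc_p, ff_p = ff_p, cat_ = cat_, fa = fa, fy = fy,
                p = p, q = q)
  list(q = q, p = p, state = state, cache = cache)
}

# ---- backward step --------------------------------------------------------

# gz: gradient wrt the softmax *input* z from the step's own loss terms;
# gq: gradient wrt q from the step's own loss; carry: gradients arriving
# from step t+1 through the recurrent state (same fields as bias3d_state;
# j_clf is wrt the post-softmax p, j_mot wrt q). Accumulates parameter
# gradients into `acc` (an environment) and returns the carry for t-1.
model_step_bwd <- function(pr, cfg, ca, gz, gq, carry, acc) {
  g <- cfg$glimpse_size; g2 <- g %/% 2L
  add <- function(name, val) acc[[name]] <- acc[[name]] + val
  p <- ca$p
  # softmax jacobian folds the carried dL/dp into dL/dz
  gj <- carry$j_clf
  gz <- gz + p * (gj - sum(gj * p))
  gq <- gq + carry$j_mot
  # heads + fusion
  add("hq_W", crossprod(ca$fy, gq)); add("hq_b", as.numeric(gq))
  add("hc_W", crossprod(ca$fy, gz)); add("hc_b", as.numeric(gz))
  gfy <- tcrossprod(gq, pr$hq_W) + tcrossprod(gz, pr$hc_W)
  gfa <- gfy * (ca$fa > 0)
  add("fus_W", crossprod(ca$cat_, gfa)); add("fus_b", as.numeric(gfa))
  gcat <- tcrossprod(gfa, pr$fus_W)
  FC <- cfg$clf_fc; FF <- cfg$mot_ff
  g_oclf <- gcat[, seq_len(FC), drop = FALSE] + carry$e_clf
  g_offm <- gcat[, FC + seq_len(FF), drop = FALSE]
  g_offp <- gcat[, FC + FF + seq_len(cfg$pos_ff), drop = FALSE]
  # classifier FCEJ + conv stack
  bc <- fcej_bwd(g_oclf, ca$fc_c, pr$clf_fc_Wx, pr$clf_fc_We, pr$clf_fc_Wj)
  add("clf_fc_Wx", bc$dWx); add("clf_fc_We", bc$dWe); add("clf_fc_Wj", bc$dWj)
  add("clf_fc_b", bc$db)
  gr3 <- matrix(bc$gx, nrow = (g2 %/% 2L)^2)
  gc3 <- gr3 * (ca$c3$y > 0)
  b3 <- cv_bwd(gc3, ca$c3, pr$clf_c3_W)
  add("clf_c3_W", b3$dW); add("clf_c3_b", b3$db)
  gr2 <- mp_bwd(b3$gx, ca$p2) * (ca$l2$y > 0)
  gl2 <- lrn_bwd(gr2, ca$l2)
  b2 <- cv_bwd(gl2, ca$c2, pr$clf_c2_W)
  add("clf_c2_W", b2$dW); add("clf_c2_b", b2$db)
  gr1 <- mp_bwd(b2$gx, ca$p1) * (ca$l1$y > 0)
  gl1 <- lrn_bwd(gr1, ca$l1)
  b1 <- cv_bwd(gl1, ca$c1, pr$clf_c1_W)
  add("clf_c1_W", b1$dW); add("clf_c1_b", b1$db)
  # motion pipeline
  bff <- jkff_bwd(g_offm, carry$H_mf, ca$ff_m, pr$mot_ff_Wj, pr$mot_ff_Wk,
                  pr$mot_ff_Wo)
  add("mot_ff_Wj", bff$dWj); add("mot_ff_Wk", bff$dWk); add("mot_ff_Wo", bff$dWo)
  bm <- fcej_bwd(bff$gx + carry$e_mot, ca$fc_m,
                 pr$mot_fc_Wx, pr$mot_fc_We, pr$mot_fc_Wj)
  add("mot_fc_Wx", bm$dWx); add("mot_fc_We", bm$dWe); add("mot_fc_Wj", bm$dWj)
  add("mot_fc_b", bm$db)
  gmp2 <- matrix(bm$gx, nrow = (g2 %/% 2L)^2)
  gmr2 <- mp_bwd(gmp2, ca$mp2) * (ca$ml2$y > 0)
  gml2 <- lrn_bwd(gmr2, ca$ml2)
  bf2 <- cjkff_bwd(gml2, carry$H_m2, ca$f2, pr$mot_f2_Wj, pr$mot_f2_Wk,
                   pr$mot_f2_Wo)
  add("mot_f2_Wj", bf2$dWj); add("mot_f2_Wk", bf2$dWk); add("mot_f2_Wo", bf2$dWo)
  gmr1 <- mp_bwd(bf2$gx, ca$mp1) * (ca$ml1$y > 0)
  gml1 <- lrn_bwd(gmr1, ca$ml1)
  bf1 <- cjkff_bwd(gml1, carry$H_m1, ca$f1, pr$mot_f1_Wj, pr$mot_f1_Wk,
                   pr$mot_f1_Wo)
  add("mot_f1_Wj", bf1$dWj); add("mot_f1_Wk", bf1$dWk); add("mot_f1_Wo", bf1$dWo)
  # position pipeline
  bpf <- jkff_bwd(g_offp, carry$H_pf, ca$ff_p, pr$pos_ff_Wj, pr$pos_ff_Wk,
                  pr$pos_ff_Wo)
  add("pos_ff_Wj", bpf$dWj); add("pos_ff_Wk", bpf$dWk); add("pos_ff_Wo", bpf$dWo)
  bp <- fcej_bwd(bpf$gx + carry$e_pos, ca$fc_p,
                 pr$pos_fc_Wx, pr$pos_fc_We, NULL)
  add("pos_fc_Wx", bp$dWx); add("pos_fc_We", bp$dWe); add("pos_fc_b", bp$db)
  # carry for step t-1
  list(e_clf = bc$ge, j_clf = bc$gj, e_mot = bm$ge, j_mot = bm$gj,
       e_pos = bp$ge, H_m1 = bf1$gH, H_m2 = bf2$gH, H_mf = bff$gH,
       H_pf = bpf$gH)
}

# ---- public wrappers ------------------------------------------------------

#' One forward step of the full recurrent model
#'
#' Runs one synchronous step of all three pipelines and both heads, and
#' returns the evolved recurrent state. Deterministic given (glimpse, theta,
#' state) and the weights.
#'
#' @param model a [bias3d_build()] network.
#' @param glimpse glimpse array from [extract_glimpse()].
#' @param theta camera azimuth in degrees.
#' @param state a [reset_state()] state (or the state from the previous call).
#' @return list with `q_values` (numeric 3-vector), `class_probs`
#'   (numeric `n+1`-vector summing to 1) and `state`.
#' @export
bias3d_forward <- function(model, glimpse, theta, state) {
  cfg <- model$config
  d <- dim(glimpse)
  if (length(d) != 3L || d[1] != cfg$glimpse_size || d[3] != cfg$glimpse_depth)
    stopf("bias3d_forward: glimpse must be %d x %d x %d",
          cfg$glimpse_size, cfg$glimpse_size, cfg$glimpse_depth)
  if (ncol(state$e_clf) != cfg$clf_fc || ncol(state$H_mf) != cfg$mot_ff)
    stopf("bias3d_forward: state does not match the model configuration")
  gm <- matrix(glimpse, d[1] * d[2], d[3])
  out <- model_step(model$params, cfg, gm, theta, state)
  list(q_values = as.numeric(out$q), class_probs = as.numeric(out$p),
       state = out$state)
}

#' Count trainable parameters
#'
#' @param model a `bias3d_net` (or a bare parameter list).
#' @return total number of trainable scalars.
#' @seealso [param_table()] for the per-layer breakdown.
#' @export
count_params <- function(model) {
  pr <- if (inherits(model, "bias3d_net")) model$params else model
  sum(vapply(pr, length, numeric(1)))
}

#' Per-layer parameter breakdown
#'
#' @param model a `bias3d_net`.
#' @return data frame with tensor name, shape and parameter count.
#' @export
param_table <- function(model) {
  pr <- if (inherits(model, "bias3d_net")) model$params else model
  data.frame(
    tensor = names(pr),
    shape = vapply(pr, function(x)
      paste(if (is.matrix(x)) dim(x) else length(x), collapse = "x"),
      character(1)),
    n = vapply(pr, length, numeric(1)),
    row.names = NULL)
}
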