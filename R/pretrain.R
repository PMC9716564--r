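# Supervised pretraining of the classifier stream. Views are collected on a
# 9-degree orbital grid around each cube, labelled target-class within
# +/-45 degrees of the target face (background outside), class-balanced by
# subsampling the background views, and the feed-forward classifier
# (conv stack + FC, no recurrence, its own softmax head) is trained with
# cross-entropy on the glimpses of those views. The trained convolutional
# and FC weights are then transplanted into the full recurrent model and
# the pretraining head is discarded.

#' Collect labelled orbital views of a cube
#'
#' Renders one view per azimuth on a grid of the given step over 0-360
#' degrees and labels each view by the signed offset from the target face:
#' target class within +/-45 degrees (inclusive), background outside.
#'
#' @param scene a [cube_scene()].
#' @param step grid step in degrees; must divide 360 (default 9: 40 views).
#' @param render_cfg a [render_config()].
#' @return list of labelled views `list(view, label, theta, offset)`;
#'   `label` is `scene$target_class` for target views and `-1L` for
#'   background views (consumers remap background to class index
#'   `n_classes`).
#' @export
collect_views <- function(scene, step = 9, render_cfg = render_config()) {
  if (step <= 0 || 360 %% step != 0)
    stopf("collect_views: step must be positive and divide 360")
  lapply(seq(0, 360 - step, by = step), function(th) {
    off <- relative_offset(th, scene)
    list(view = render(scene, camera_pose(th), render_cfg),
         label = if (abs(off) <= 45) scene$target_class else -1L,
         theta = th, offset = off)
  })
}

#' Balance target and background views
#'
#' Keeps every target-labelled view and subsamples the background views
#' without replacement down to the same count. If there are fewer
#' background views than target views, all are kept and the imbalance is
#' flagged in the `balanced` attribute.
#'
#' @param views output of [collect_views()].
#' @param seed optional integer seed for the subsample.
#' @return balanced list of views, with attribute `balanced` (logical).
#' @export
balance_views <- function(views, seed = NULL) {
  labs <- vapply(views, `[[`, integer(1), "label")
  ti <- which(labs >= 0L)
  bi <- which(labs < 0L)
  if (length(ti) == 0) stopf("balance_views: no target-labelled views")
  keep_b <- if (length(bi) > length(ti))
    with_seed(seed, sample(bi, length(ti))) else bi
  out <- views[sort(c(ti, keep_b))]
  attr(out, "balanced") <- length(keep_b) == length(ti)
  out
}

# ---- feed-forward classifier net ------------------------------------------

build_pretrain_net <- function(cfg, seed = 1L) {
  Cg <- cfg$glimpse_depth
  k1 <- cfg$clf_conv[1]; k2 <- cfg$clf_conv[2]; k3 <- cfg$clf_conv[3]
  pr <- with_seed(seed, list(
    c1_W = xavier_init(9L * Cg, k1), c1_b = numeric(k1),
    c2_W = xavier_init(9L * k1, k2), c2_b = numeric(k2),
    c3_W = xavier_init(9L * k2, k3), c3_b = numeric(k3),
    fc_W = xavier_init(cfg$flat_clf, cfg$clf_fc), fc_b = numeric(cfg$clf_fc),
    hd_W = xavier_init(cfg$clf_fc, cfg$n_out), hd_b = numeric(cfg$n_out)))
  structure(list(params = pr, config = cfg), class = "bias3d_pretrain")
}

pre_fwd <- function(pr, cfg, gm) {
  g <- cfg$glimpse_size; g2 <- g %/% 2L
  band <- function(C) cfg$bands[[as.character(C)]]
  lk <- cfg$lrn_k; la <- cfg$lrn_alpha; lb <- cfg$lrn_beta
  c1 <- cv_fwd(gm, g, g, pr$c1_W, pr$c1_b); c1$h <- g; c1$w <- g
  l1 <- lrn_fwd(c1$y, lk, la, lb, NA, M = band(cfg$clf_conv[1]))
  r1 <- relu(l1$y); p1 <- mp_fwd(r1, g, g)
  c2 <- cv_fwd(p1$y, g2, g2, pr$c2_W, pr$c2_b); c2$h <- g2; c2$w <- g2
  l2 <- lrn_fwd(c2$y, lk, la, lb, NA, M = band(cfg$clf_conv[2]))
  r2 <- relu(l2$y); p2 <- mp_fwd(r2, g2, g2)
  c3 <- cv_fwd(p2$y, g2 %/% 2L, g2 %/% 2L, pr$c3_W, pr$c3_b)
  c3$h <- g2 %/% 2L; c3$w <- g2 %/% 2L
  r3 <- relu(c3$y)
  flat <- matrix(r3, 1L)
  a <- flat %*% pr$fc_W + rep(pr$fc_b, each = 1L)
  fy <- relu(a)
  z <- fy %*% pr$hd_W + rep(pr$hd_b, each = 1L)
  p <- matrix(softmax(z), 1L)
  list(p = p, cache = list(c1 = c1, l1 = l1, p1 = p1, c2 = c2, l2 = l2,
                           p2 = p2, c3 = c3, flat = flat, a = a, fy = fy,
                           p = p))
}

# Accumulate cross-entropy gradients for one sample into `acc`.
pre_bwd <- function(pr, cfg, ca, d_onehot, acc, w = 1) {
  add <- function(nm, v) acc[[nm]] <- acc[[nm]] + v
  gz <- (ca$p - matrix(d_onehot, 1L)) * w
  add("hd_W", crossprod(ca$fy, gz)); add("hd_b", as.numeric(gz))
  gfy <- tcrossprod(gz, pr$hd_W)
  ga <- gfy * (ca$a > 0)
  add("fc_W", crossprod(ca$flat, ga)); add("fc_b", as.numeric(ga))
  g2h <- cfg$glimpse_size %/% 4L
  gr3 <- matrix(tcrossprod(ga, pr$fc_W), nrow = g2h * g2h)
  gc3 <- gr3 * (ca$c3$y > 0)
  b3 <- cv_bwd(gc3, ca$c3, pr$c3_W)
  add("c3_W", b3$dW); add("c3_b", b3$db)
  gr2 <- mp_bwd(b3$gx, ca$p2) * (ca$l2$y > 0)
  b2 <- cv_bwd(lrn_bwd(gr2, ca$l2), ca$c2, pr$c2_W)
  add("c2_W", b2$dW); add("c2_b", b2$db)
  gr1 <- mp_bwd(b2$gx, ca$p1) * (ca$l1$y > 0)
  b1 <- cv_bwd(lrn_bwd(gr1, ca$l1), ca$c1, pr$c1_W)
  add("c1_W", b1$dW); add("c1_b", b1$db)
  invisible(NULL)
}

# Class probabilities of the pretrained classifier for one glimpse matrix.
pretrain_predict <- function(pre, gm) {
  as.numeric(.cpp_pre_predict(pre$params, pre$config, list(gm)))
}

# Build the balanced glimpse training set from a list of cubes.
pretrain_dataset <- function(cubes, cfg, step = 9, seed = 1L,
                             render_cfg = render_config(),
                             glimpse_cfg = glimpse_config()) {
  seeds <- derive_seeds(seed, length(cubes))
  g <- glimpse_cfg$out_size
  X <- list(); y <- integer(0)
  for (i in seq_along(cubes)) {
    vs <- balance_views(collect_views(cubes[[i]], step, render_cfg),
                        seed = seeds[i])
    for (v in vs) {
      gl <- extract_glimpse(v$view, glimpse_cfg)
      X[[length(X) + 1L]] <- matrix(gl, g * g, dim(gl)[3])
      y <- c(y, if (v$label < 0L) cfg$n_classes else v$label)
    }
  }
  list(X = X, y = y)
}

#' Pretrain the feed-forward classifier on orbital views
#'
#' Trains the classifier pipeline (conv/LRN/pool stack and FC layer, no
#' recurrence) with cross-entropy on glimpses of class-balanced orbital
#' views of the training cubes, using minibatch Adam.
#'
#' @param cubes list of [cube_scene()] training cubes.
#' @param config a [bias3d_config()] fixing the architecture widths.
#' @param epochs training epochs (default 8).
#' @param lr Adam learning rate (default 1e-3).
#' @param batch_size minibatch size (default 32).
#' @param step view-collection grid in degrees (default 9).
#' @param seed integer seed.
#' @param dataset optionally, a prebuilt glimpse dataset as returned by the
#'   internal `pretrain_dataset()` (lets callers reuse rendered views).
#' @param engine `"cpp"` (compiled batch updates, default) or `"r"` (pure-R
#'   reference path).
#' @return object of class `bias3d_pretrain` with elements `params`,
#'   `config` and `history` (per-epoch mean loss and training accuracy).
#' @export
pretrain_classifier <- function(cubes, config, epochs = 12L, lr = 1e-3,
                                batch_size = 32L, step = 9, seed = 1L,
                                dataset = NULL, engine = c("cpp", "r")) {
  if (length(cubes) == 0 && is.null(dataset))
    stopf("pretrain_classifier: no training cubes")
  engine <- match.arg(engine)
  seeds <- derive_seeds(seed, 3L)
  ds <- dataset %||% pretrain_dataset(cubes, config, step = step,
                                      seed = seeds[1])
  if (length(unique(ds$y)) < config$n_out)
    stopf("pretrain_classifier: not all %d classes present in the views",
          config$n_out)
  net <- build_pretrain_net(config, seed = seeds[2])
  pr <- net$params
  opt <- adam_init(pr)
  n <- length(ds$X)
  hist <- data.frame(epoch = seq_len(epochs), loss = NA_real_, acc = NA_real_)
  ord_seeds <- derive_seeds(seeds[3], epochs)
  for (ep in seq_len(epochs)) {
    ord <- with_seed(ord_seeds[ep], sample(n))
    tot_loss <- 0; tot_correct <- 0
    for (b0 in seq(1, n, by = batch_size)) {
      bi <- ord[b0:min(b0 + batch_size - 1L, n)]
      if (engine == "cpp") {
        bt <- .cpp_pre_batch(pr, config, ds$X, ds$y, bi)
        gr <- bt$grads
        tot_loss <- tot_loss + bt$loss
        tot_correct <- tot_correct + bt$correct
      } else {
        acc <- new.env(parent = emptyenv())
        for (nm in names(pr)) acc[[nm]] <- 0 * pr[[nm]]
        for (i in bi) {
          f <- pre_fwd(pr, config, ds$X[[i]])
          d <- onehot(ds$y[i], config$n_out)
          pre_bwd(pr, config, f$cache, d, acc, w = 1 / length(bi))
          tot_loss <- tot_loss - log(f$p[1, ds$y[i] + 1L] + 1e-12)
          tot_correct <- tot_correct + (which.max(f$p) == ds$y[i] + 1L)
        }
        gr <- lapply(stats::setNames(nm = names(pr)), function(nm) acc[[nm]])
      }
      up <- adam_step(pr, gr, opt, lr)
      pr <- up$params; opt <- up$opt
    }
    hist$loss[ep] <- tot_loss / n
    hist$acc[ep] <- tot_correct / n
  }
  structure(list(params = pr, config = config, history = hist),
            class = "bias3d_pretrain")
}

#' Held-out view accuracy of a pretrained classifier
#'
#' Collects balanced orbital views of the given cubes and reports the
#' fraction classified correctly from their glimpses.
#'
#' @param pre a `bias3d_pretrain` object.
#' @param cubes held-out cubes.
#' @param step view grid in degrees.
#' @param seed seed for the balancing subsample.
#' @return accuracy in `[0, 1]`.
#' @export
pretrain_accuracy <- function(pre, cubes, step = 9, seed = 1L) {
  cfg <- pre$config
  ds <- pretrain_dataset(cubes, cfg, step = step, seed = seed)
  P <- .cpp_pre_predict(pre$params, cfg, ds$X)
  mean(max.col(P, ties.method = "first") == ds$y + 1L)
}

#' Load pretrained classifier weights into the full model
#'
#' Copies the convolutional and FC weights of a pretrained classifier into
#' the classifier pipeline of a full `bias3d_net`. With `warm_start = TRUE`
#' (the default) the classification capability itself is carried over as
#' well: the classifier-pipeline context weights (Elman, Jordan) start at
#' zero, the fusion layer starts as an identity block that passes the
#' classifier features through (remaining fusion weights damped), and the
#' pretrained softmax head is written into the classification head on those
#' pass-through coordinates. The full model then classifies like the
#' pretrained network from the first step, and the recurrent pathways grow
#' from there during end-to-end training - without this, the classification
#' head must relearn from scratch inside the RL loop and the confidence-
#' gated reward stays silent for a long time. With `warm_start = FALSE`
#' only the conv/FC weights are copied and the pretraining head is
#' discarded.
#'
#' @param model a `bias3d_net` from [bias3d_build()].
#' @param pre a `bias3d_pretrain` from [pretrain_classifier()].
#' @param warm_start carry the head and identity-initialise the fusion
#'   block (default `TRUE`).
#' @param damp scale applied to the random mixing weights of the
#'   non-pass-through fusion units under `warm_start` (default 1: keep the
#'   Xavier initialization).
#' @return the model with transplanted classifier weights.
#' @export
transplant_classifier <- function(model, pre, warm_start = TRUE,
                                  damp = 1) {
  stopifnot(inherits(model, "bias3d_net"), inherits(pre, "bias3d_pretrain"))
  pp <- pre$params
  model$params$clf_c1_W <- pp$c1_W; model$params$clf_c1_b <- pp$c1_b
  model$params$clf_c2_W <- pp$c2_W; model$params$clf_c2_b <- pp$c2_b
  model$params$clf_c3_W <- pp$c3_W; model$params$clf_c3_b <- pp$c3_b
  model$params$clf_fc_Wx <- pp$fc_W; model$params$clf_fc_b <- pp$fc_b
  if (warm_start) {
    cfg <- model$config
    FCw <- cfg$clf_fc; U <- cfg$fusion
    stopifnot(U > FCw)
    # contexts start silent; their weights remain trainable
    model$params$clf_fc_We <- 0 * model$params$clf_fc_We
    model$params$clf_fc_Wj <- 0 * model$params$clf_fc_Wj
    # the first FCw fusion units become an exact pass-through of the
    # classifier features (identity block, no motion/position cross-talk);
    # the remaining U - FCw units keep their random mixing, scaled by
    # `damp`, so the Q head retains live pathways from all pipelines
    model$params$fus_W[, seq_len(FCw)] <- 0
    model$params$fus_W[seq_len(FCw), seq_len(FCw)] <- diag(FCw)
    model$params$fus_W[, (FCw + 1):U] <- damp * model$params$fus_W[, (FCw + 1):U]
    # classification head: the pretrained read-out on the pass-through
    # units, silent elsewhere (those rows remain trainable)
    model$params$hc_W <- 0 * model$params$hc_W
    model$params$hc_W[seq_len(FCw), ] <- pp$hd_W
    model$params$hc_b <- pp$hd_b
    # Q head starts at zero: Q-values are built purely from the reward
    # signal rather than initialization noise, and - with the lowest-index
    # tie-break of the action selector - the early greedy policy is a
    # deterministic sweep instead of parking on argmax-of-noise states
    model$params$hq_W <- 0 * model$params$hq_W
    model$params$hq_b <- 0 * model$params$hq_b
  }
  model
}
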