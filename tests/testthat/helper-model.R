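# Tiny architectures and a from-scratch episode loss used to finite-
# difference-check the backpropagation-through-time implementation.

# lrn_k = 1 keeps the normalization well-conditioned so central differences
# are trustworthy; the k = 0 backward is finite-difference-checked in
# isolation in test-layers.R.
tiny_config <- function(n_classes = 2L, C = 1L, lrn_k = 1) {
  bias3d_config(n_classes = n_classes, input_channels = C, preset = "small",
                glimpse_size = 8L, lrn_k = lrn_k,
                clf_conv = c(2L, 2L, 2L), clf_fc = 4L,
                mot_conv = c(2L, 2L), mot_fc = 4L, mot_ff = 3L,
                pos_fc = 3L, pos_ff = 2L, fusion = 5L)
}

rand_glimpse_mat <- function(cfg) {
  matrix(runif(cfg$glimpse_size^2 * cfg$glimpse_depth),
         cfg$glimpse_size^2, cfg$glimpse_depth)
}

# Episode loss as an explicit function of the parameters, holding the
# trajectory (glimpses, thetas, actions), the rewards and the bootstrap
# targets fixed - exactly the quantity the analytic backward differentiates
# (weighted CE over steps, background steps down-weighted, plus TD MSE).
episode_loss_fn <- function(pr, cfg, gms, thetas, actions, labels,
                            rew, qnext_max, gamma, bg_w = 0.25) {
  T_ <- length(actions)
  st <- reset_state(cfg)
  P <- matrix(0, T_, cfg$n_out); D <- matrix(0, T_, cfg$n_out)
  td <- numeric(T_)
  for (t in seq_len(T_)) {
    out <- bias3d:::model_step(pr, cfg, gms[[t]], thetas[t], st)
    st <- out$state
    P[t, ] <- out$p
    D[t, labels[t] + 1L] <- 1
    td[t] <- rew[t] + gamma * qnext_max[t] - out$q[1, actions[t]]
  }
  wts <- ifelse(labels == cfg$n_classes, bg_w, 1)
  ce <- sum(wts * -rowSums(D * log(P + 1e-12))) / sum(wts)
  ce + mean(td^2)
}
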