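# Denoising diffusion model over the encoded table representation: a
# standard DDPM with a linear beta schedule, an MLP denoiser predicting the
# added noise (mean-squared-error loss), and ancestral sampling. One-hot
# blocks are treated as continuous coordinates during diffusion and
# re-argmaxed at decode time.

time_embedding <- function(t, n_steps) {
  x <- t / n_steps
  cbind(x, sin(2 * pi * x), cos(2 * pi * x),
        sin(4 * pi * x), cos(4 * pi * x), sin(8 * pi * x))
}

#' Train a diffusion generator state
#'
#' Each minibatch draws a uniform step `t` per row, forms
#' `x_t = sqrt(abar_t) x_0 + sqrt(1 - abar_t) eps` and regresses the
#' denoiser output on `eps`. The learning rate decays linearly to zero over
#' the configured epoch budget (per-epoch granularity), tracked on the state
#' so resumed training continues the schedule.
#'
#' @param state a `diffusion` [generator_state()].
#' @param table training `clinical_table`.
#' @param epochs number of epochs.
#' @return the state, trained in place.
#' @export
train_diffusion <- function(state, table, epochs = state$config$epochs) {
  cfg <- state$config
  tr <- state$tr
  key <- c(nrow(table$data), sum(table$data[[1]]))
  if (is.null(state$cache_key) || !identical(state$cache_key, key)) {
    state$cache_enc <- transform_table(table, tr,
                                       seed = derive_seed(state$seed, "encode"))$X
    state$cache_key <- key
  }
  X <- state$cache_enc
  n <- nrow(X); d <- ncol(X)
  Tn <- cfg$n_steps
  with_state_rng(state, {
    for (ep in seq_len(epochs)) {
      lr <- cfg$lr * max(0.01, 1 - state$epochs_done / max(cfg$epochs, 1))
      ord <- sample.int(n)
      starts <- seq(1, n, by = cfg$batch_size)
      for (s in starts) {
        ix <- ord[s:min(s + cfg$batch_size - 1, n)]
        x0 <- X[ix, , drop = FALSE]
        b <- length(ix)
        t <- sample.int(Tn, b, replace = TRUE)
        ab <- state$alpha_bar[t]
        eps <- matrix(stats::rnorm(b * d), b)
        xt <- x0 * sqrt(ab) + eps * sqrt(1 - ab)
        inp <- cbind(xt, time_embedding(t, Tn))
        fwd <- mlp3_forward(state$params, inp, "relu")
        resid <- fwd$out - eps
        grads <- mlp3_backward(state$params, fwd, 2 * resid / length(resid))$grads
        upd <- adam_step(state$params, grads, state$opt, lr,
                         cfg$beta1, cfg$beta2)
        state$params <- upd$params; state$opt <- upd$opt
      }
      state$epochs_done <- state$epochs_done + 1
    }
  })
  state
}

sample_diffusion <- function(state, m, seed = 1) {
  cfg <- state$config
  tr <- state$tr
  d <- tr$width
  Tn <- cfg$n_steps
  X <- with_seed(seed, {
    x <- matrix(stats::rnorm(m * d), m)
    for (t in Tn:1) {
      inp <- cbind(x, time_embedding(rep(t, m), Tn))
      eps_hat <- mlp3_forward(state$params, inp, "relu")$out
      a <- state$alphas[t]; ab <- state$alpha_bar[t]
      x <- (x - eps_hat * (1 - a) / sqrt(1 - ab)) / sqrt(a)
      if (t > 1) {
        ab_prev <- state$alpha_bar[t - 1]
        sigma <- sqrt((1 - ab_prev) / (1 - ab) * state$betas[t])
        x <- x + sigma * matrix(stats::rnorm(m * d), m)
      }
    }
    x
  })
  inverse_transform(X, tr)
}
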