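# Conditional tabular GAN: WGAN with gradient penalty, training-by-sampling
# over categorical columns, pac-grouped discriminator, tanh on normalized
# continuous scalars and Gumbel-softmax (temperature `tau`) on every one-hot
# block. The paper fixes only hyperparameters; internals follow the standard
# reference design at these sizes: a batch-normalised ReLU generator and a
# leaky-ReLU discriminator with dropout 0.5 over pac-grouped inputs.

# -- conditional sampler ------------------------------------------------------

# Training-by-sampling state: per categorical column, log-frequency level
# probabilities and the row indices per level.
build_cond_sampler <- function(cond, table) {
  if (is.null(cond)) return(NULL)
  samplers <- lapply(cond$blocks, function(b) {
    codes <- table$data[[b$col]]
    counts <- tabulate(codes, nbins = b$width)
    lp <- log1p(counts)
    lp <- if (sum(lp) > 0) lp / sum(lp) else rep(1 / b$width, b$width)
    list(probs = lp,                 # log-frequency: training-by-sampling
         raw_probs = counts / max(sum(counts), 1),  # original: generation
         rows = split(seq_along(codes), factor(codes, seq_len(b$width))))
  })
  names(samplers) <- names(cond$blocks)
  samplers
}

# Draw B conditioning vectors (vectorised by block/level): returns the cond
# matrix, matching real row indices and the (block, level) choices for the
# generator cross-entropy term.
draw_condition <- function(cond, samplers, B) {
  nb <- length(cond$blocks)
  blk_ix <- sample.int(nb, B, replace = TRUE)
  lvl <- integer(B)
  rows <- integer(B)
  for (bi in seq_len(nb)) {
    at <- which(blk_ix == bi)
    if (length(at) == 0) next
    b <- cond$blocks[[bi]]; s <- samplers[[bi]]
    pr <- s$probs
    seen <- lengths(s$rows) > 0
    if (!all(seen)) pr <- pr * seen      # never condition on locally absent levels
    l <- sample.int(b$width, length(at), replace = TRUE, prob = pr)
    lvl[at] <- l
    for (li in unique(l)) {
      sub <- at[l == li]
      cand <- s$rows[[li]]
      rows[sub] <- cand[sample.int(length(cand), length(sub), replace = TRUE)]
    }
  }
  C <- matrix(0, B, cond$dim)
  off <- vapply(cond$blocks, `[[`, 0L, "cond_offset")
  C[cbind(seq_len(B), off[blk_ix] + lvl)] <- 1
  list(C = C, rows = rows, blk = blk_ix, lvl = lvl)
}

# -- output activation --------------------------------------------------------

row_max <- function(M) M[cbind(seq_len(nrow(M)), max.col(M, ties.method = "first"))]

softmax_rows <- function(Z) {
  Z <- Z - row_max(Z)
  E <- exp(Z)
  E / rowSums(E)
}

# Activate raw generator outputs: tanh on each continuous alpha slot,
# Gumbel-softmax on every one-hot block. Returns the activated matrix and
# per-block softmax caches for the backward pass.
ctgan_activate <- function(raw, tr, tau, gumbel = TRUE) {
  out <- raw
  caches <- list()
  for (nm in tr$columns) {
    lay <- tr$layout[[nm]]
    if (lay$type == "gmm") {
      j <- lay$offset + 1L
      out[, j] <- tanh(raw[, j])
      blocks <- lay$offset + 1L + seq_len(lay$width - 1L)
    } else {
      blocks <- lay$offset + seq_len(lay$width)
    }
    logits <- raw[, blocks, drop = FALSE]
    if (gumbel) {
      u <- matrix(stats::runif(length(logits)), nrow(logits))
      logits <- logits - log(-log(pmax(u, 1e-12)))
    }
    sm <- softmax_rows(logits / tau)
    out[, blocks] <- sm
    caches[[nm]] <- list(blocks = blocks, sm = sm)
  }
  list(out = out, caches = caches)
}

# Backward through the activation: dAct (grad w.r.t. activated outputs) to
# dRaw (grad w.r.t. raw logits), at the sampled Gumbel noise.
ctgan_activate_backward <- function(dAct, act, tr, tau) {
  dRaw <- dAct
  for (nm in tr$columns) {
    lay <- tr$layout[[nm]]
    if (lay$type == "gmm") {
      j <- lay$offset + 1L
      dRaw[, j] <- dAct[, j] * (1 - act$out[, j]^2)
    }
    cache <- act$caches[[nm]]
    y <- cache$sm
    dy <- dAct[, cache$blocks, drop = FALSE]
    dRaw[, cache$blocks] <- (y * (dy - rowSums(dy * y))) / tau
  }
  dRaw
}

# pac grouping: stack every `pac` consecutive rows into one wide row.
pac_group <- function(X, pac) matrix(t(X), nrow = nrow(X) / pac, byrow = TRUE)
pac_ungroup <- function(Xg, pac, d) matrix(t(Xg), ncol = d, byrow = TRUE)

# -- training -----------------------------------------------------------------

split_params <- function(state, prefix) {
  p <- state$params[grep(paste0("^", prefix, "_"), names(state$params))]
  names(p) <- sub(paste0("^", prefix, "_"), "", names(p))
  p
}

merge_params <- function(state, prefix, p) {
  names(p) <- paste0(prefix, "_", names(p))
  for (nm in names(p)) state$params[[nm]] <- p[[nm]]
}

# Effective batch for a client table: the configured batch, capped at the
# local sample count rounded down to a pac multiple (training on more rows
# per step than a client owns adds compute without information).
ctgan_batch <- function(cfg, n) {
  max(cfg$pac, min(cfg$batch_size, (n %/% cfg$pac) * cfg$pac))
}

#' Train a conditional tabular GAN state
#'
#' One step per batch: the discriminator (Wasserstein loss with gradient
#' penalty over pac groups) is updated along with the generator, whose loss
#' adds the cross-entropy between the sampled conditioning one-hot and its
#' generated block. The training table is encoded once per call with a mode
#' seed derived from the state seed, so resumed training sees the identical
#' encoding.
#'
#' @param state a `ctgan` [generator_state()].
#' @param table training `clinical_table`.
#' @param epochs number of epochs.
#' @return the state, trained in place.
#' @export
train_ctgan <- function(state, table, epochs = state$config$epochs) {
  cfg <- state$config
  tr <- state$tr
  cond <- state$cond
  # encoding and conditional sampler are deterministic given (state seed,
  # table); cache them so per-round federated calls skip re-encoding
  key <- c(nrow(table$data), sum(table$data[[1]]))
  if (is.null(state$cache_key) || !identical(state$cache_key, key)) {
    state$cache_enc <- transform_table(table, tr,
                                       seed = derive_seed(state$seed, "encode"))$X
    state$cache_samplers <- build_cond_sampler(cond, table)
    state$cache_key <- key
  }
  X <- state$cache_enc
  n <- nrow(X); d <- ncol(X)
  cdim <- if (is.null(cond)) 0L else cond$dim
  samplers <- state$cache_samplers
  state$cond_samplers <- samplers
  B <- ctgan_batch(cfg, n)
  pac <- cfg$pac
  steps <- max(1L, n %/% B)
  ng <- B / pac
  gp <- split_params(state, "g")
  dp <- split_params(state, "d")
  gen_batch <- function() {
    cd <- if (cdim > 0) draw_condition(cond, samplers, B)
    C <- if (cdim > 0) cd$C else matrix(0, B, 0)
    Z <- matrix(stats::rnorm(B * cfg$embedding_dim), B)
    gfwd <- gnet_forward_train(gp, state$buffers, cbind(Z, C))
    state$buffers <- gfwd$buf
    act <- ctgan_activate(gfwd$out, tr, cfg$tau)
    list(cd = cd, C = C, gfwd = gfwd, act = act)
  }
  with_state_rng(state, {
    for (ep in seq_len(epochs)) {
      for (s in seq_len(steps)) {
        ## ---- discriminator step
        gb <- gen_batch()
        real_ix <- if (cdim > 0) gb$cd$rows else sample.int(n, B, replace = TRUE)
        Rg <- pac_group(cbind(X[real_ix, , drop = FALSE], gb$C), pac)
        Fg <- pac_group(cbind(gb$act$out, gb$C), pac)
        fr <- dnet_forward(dp, Rg)
        ff <- dnet_forward(dp, Fg)
        eps <- stats::runif(ng)
        fi <- dnet_forward(dp, Rg * eps + Fg * (1 - eps))
        ig <- mlp3_input_grad(dp, fi)
        d_gr <- mlp3_backward(dp, fr, matrix(-1 / ng, ng, 1))$grads
        d_gf <- mlp3_backward(dp, ff, matrix(1 / ng, ng, 1))$grads
        d_gp <- gp_param_grads(dp, fi, ig, cfg$gp_lambda)
        dgrads <- Map(function(a, b, cg) a + b + cg, d_gr, d_gf, d_gp)
        upd <- adam_step(dp, dgrads, state$opt_d, cfg$lr,
                         cfg$beta1, cfg$beta2, wd = cfg$weight_decay)
        dp <- upd$params; state$opt_d <- upd$opt
        ## ---- generator step
        gb <- gen_batch()
        Fg <- pac_group(cbind(gb$act$out, gb$C), pac)
        ff <- dnet_forward(dp, Fg)
        bk <- mlp3_backward(dp, ff, matrix(-1 / ng, ng, 1))
        dXf <- pac_ungroup(bk$dX, pac, d + cdim)[, seq_len(d), drop = FALSE]
        dRaw <- ctgan_activate_backward(dXf, gb$act, tr, cfg$tau)
        if (cdim > 0) {
          # conditioning cross-entropy on the conditioned block's raw logits
          for (bi in seq_along(cond$blocks)) {
            at <- which(gb$cd$blk == bi)
            if (length(at) == 0) next
            b <- cond$blocks[[bi]]
            cols <- b$data_offset + seq_len(b$width)
            sm <- softmax_rows(gb$gfwd$out[at, cols, drop = FALSE])
            sm[cbind(seq_along(at), gb$cd$lvl[at])] <-
              sm[cbind(seq_along(at), gb$cd$lvl[at])] - 1
            dRaw[at, cols] <- dRaw[at, cols] + sm / B
          }
        }
        ggrads <- gnet_backward(gp, gb$gfwd, dRaw)
        upd <- adam_step(gp, ggrads, state$opt_g, cfg$lr,
                         cfg$beta1, cfg$beta2, wd = cfg$weight_decay)
        gp <- upd$params; state$opt_g <- upd$opt
      }
      state$epochs_done <- state$epochs_done + 1
    }
  })
  merge_params(state, "g", gp)
  merge_params(state, "d", dp)
  state
}

# -- sampling -----------------------------------------------------------------

sample_ctgan <- function(state, m, seed = 1) {
  cfg <- state$config
  tr <- state$tr
  cond <- state$cond
  cdim <- if (is.null(cond)) 0L else cond$dim
  gp <- split_params(state, "g")
  X <- with_seed(seed, {
    C <- matrix(0, m, cdim)
    if (cdim > 0) {
      samplers <- state$cond_samplers
      blk_ix <- sample.int(length(cond$blocks), m, replace = TRUE)
      for (bi in seq_along(cond$blocks)) {
        at <- which(blk_ix == bi)
        if (length(at) == 0) next
        b <- cond$blocks[[bi]]
        pr <- if (!is.null(samplers)) samplers[[bi]]$raw_probs
              else rep(1 / b$width, b$width)
        l <- sample.int(b$width, length(at), replace = TRUE, prob = pr)
        C[cbind(at, b$cond_offset + l)] <- 1
      }
    }
    Z <- matrix(stats::rnorm(m * cfg$embedding_dim), m)
    raw <- gnet_forward_eval(gp, state$buffers, cbind(Z, C))
    ctgan_activate(raw, tr, cfg$tau)$out
  })
  inverse_transform(X, tr)
}
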