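# Generator state: one mutable environment per model instance holding the
# model kind, configuration, trainable parameters, optimizer state and the
# model's own RNG stream. The flat-weight view (get_weights/set_weights)
# is what federated averaging operates on; its ordering is the parameter
# list order with column-major matrix entries, stable across processes.

#' Conditional tabular GAN configuration
#'
#' Defaults follow the reference implementation at study scale: two 256-unit
#' hidden layers in both networks, learning rate 2e-4 with weight decay
#' 1e-6, batch size 500, embedding (noise) dimension 128, pac 10, 500
#' epochs. `tau` is the Gumbel-softmax temperature on one-hot output blocks
#' and `gp_lambda` the gradient-penalty weight.
#'
#' @param epochs training epochs.
#' @param batch_size samples per step (must be divisible by `pac`).
#' @param embedding_dim noise input dimension.
#' @param generator_hidden,discriminator_hidden hidden layer widths.
#' @param lr learning rate for both networks.
#' @param weight_decay L2 decay for both networks.
#' @param pac discriminator sample-group size.
#' @param tau Gumbel-softmax temperature.
#' @param gp_lambda gradient penalty weight.
#' @param beta1,beta2 Adam moment decays.
#' @return a `ctgan_config` list.
#' @export
ctgan_config <- function(epochs = 500, batch_size = 500, embedding_dim = 128,
                         generator_hidden = c(256, 256),
                         discriminator_hidden = c(256, 256),
                         lr = 2e-4, weight_decay = 1e-6, pac = 10,
                         tau = 0.2, gp_lambda = 10,
                         beta1 = 0.5, beta2 = 0.9) {
  stopifnot(batch_size %% pac == 0, lr > 0, weight_decay >= 0)
  structure(list(epochs = epochs, batch_size = batch_size,
                 embedding_dim = embedding_dim,
                 generator_hidden = generator_hidden,
                 discriminator_hidden = discriminator_hidden,
                 lr = lr, weight_decay = weight_decay, pac = pac,
                 tau = tau, gp_lambda = gp_lambda,
                 beta1 = beta1, beta2 = beta2),
            class = "ctgan_config")
}

#' Denoising diffusion model configuration
#'
#' Defaults follow the reference tabular diffusion setup: 500 diffusion
#' steps, a {512, 512} MLP denoiser, learning rate 1e-4 with a linear
#' per-epoch decay, batch size 500 and a linear beta schedule from 1e-4 to
#' 0.02.
#'
#' @param epochs training epochs.
#' @param n_steps diffusion steps T.
#' @param mlp_hidden denoiser hidden widths.
#' @param lr base learning rate (decayed linearly to 0 over `epochs`).
#' @param batch_size rows per minibatch.
#' @param beta_start,beta_end linear noise schedule endpoints.
#' @param beta1,beta2 Adam moment decays.
#' @return a `diffusion_config` list.
#' @export
diffusion_config <- function(epochs = 500, n_steps = 500,
                             mlp_hidden = c(512, 512), lr = 1e-4,
                             batch_size = 500,
                             beta_start = 1e-4, beta_end = 0.02,
                             beta1 = 0.9, beta2 = 0.999) {
  stopifnot(n_steps >= 1, beta_start > 0, beta_start < beta_end, beta_end < 1)
  structure(list(epochs = epochs, n_steps = n_steps, mlp_hidden = mlp_hidden,
                 lr = lr, batch_size = batch_size,
                 beta_start = beta_start, beta_end = beta_end,
                 beta1 = beta1, beta2 = beta2),
            class = "diffusion_config")
}

default_model_config <- function(kind) {
  switch(kind, ctgan = ctgan_config(), diffusion = diffusion_config(),
         resampler = list(epochs = 1))
}

# Conditional-vector geometry: one slot per categorical level, in layout
# order. Returns NULL when the schema has no categorical columns.
cond_spec_from_layout <- function(tr) {
  cats <- Filter(function(nm) tr$layout[[nm]]$type == "onehot", tr$columns)
  if (length(cats) == 0) return(NULL)
  off <- 0L; blocks <- list()
  for (nm in cats) {
    w <- tr$layout[[nm]]$width
    blocks[[nm]] <- list(col = nm, cond_offset = off,
                         data_offset = tr$layout[[nm]]$offset, width = w)
    off <- off + w
  }
  list(blocks = blocks, dim = off, cols = cats)
}

#' Create a fresh generator state
#'
#' @param kind `"ctgan"`, `"diffusion"` or `"resampler"` (a bootstrap
#'   baseline that resamples its training rows; used as the fast stub in
#'   protocol tests).
#' @param tr the fitted [fit_transformer()] shared by all clients.
#' @param config a [ctgan_config()] / [diffusion_config()]; defaults per kind.
#' @param seed integer seed for weight initialisation and the state's own
#'   RNG stream.
#' @return a `generator_state` environment.
#' @export
generator_state <- function(kind, tr, config = NULL, seed = 1) {
  kind <- match.arg(kind, c("ctgan", "diffusion", "resampler"))
  config <- config %||% default_model_config(kind)
  st <- new.env(parent = emptyenv())
  st$kind <- kind; st$config <- config; st$tr <- tr; st$seed <- seed
  st$rng <- rng_state_new(seed)
  st$epochs_done <- 0
  d <- tr$width
  if (kind == "ctgan") {
    cs <- cond_spec_from_layout(tr)
    st$cond <- cs
    cdim <- if (is.null(cs)) 0L else cs$dim
    gh <- config$generator_hidden; dh <- config$discriminator_hidden
    with_state_rng(st, {
      st$params <- c(
        stats::setNames(gnet_init(config$embedding_dim + cdim, gh[1], gh[2], d),
                        paste0("g_", c("W1", "g1", "be1", "W2", "g2", "be2",
                                       "W3", "b3"))),
        stats::setNames(mlp3_init(config$pac * (d + cdim), dh[1], dh[2], 1),
                        paste0("d_", c("W1", "b1", "W2", "b2", "W3", "b3"))))
    })
    # batch-norm running statistics: not optimised, but part of the flat
    # weight view so federated averaging aggregates them (as the usual FL
    # client-weight serialisation does)
    st$buffers <- gnet_buffers_init(gh[1], gh[2])
    st$opt_g <- adam_init(split_params(st, "g"))
    st$opt_d <- adam_init(split_params(st, "d"))
  } else if (kind == "diffusion") {
    temb <- 6L
    with_state_rng(st, {
      st$params <- mlp3_init(d + temb, config$mlp_hidden[1],
                             config$mlp_hidden[2], d)
    })
    st$opt <- adam_init(st$params)
    sch <- seq(config$beta_start, config$beta_end, length.out = config$n_steps)
    st$betas <- sch
    st$alphas <- 1 - sch
    st$alpha_bar <- cumprod(st$alphas)
  } else {
    st$params <- list(marker = matrix(0, 1, 1))
    st$train_rows <- NULL
  }
  if (is.null(st$buffers)) st$buffers <- list()
  class(st) <- c(paste0(kind, "_state"), "generator_state")
  st
}

#' Flat weight vector of a generator state
#'
#' Trainable parameters first (parameter-list order, column-major matrix
#' entries), then any normalisation buffers; the ordering is stable across
#' processes.
#'
#' @param state a `generator_state`.
#' @return numeric weight vector.
#' @export
get_weights <- function(state)
  c(flatten_params(state$params), flatten_params(state$buffers))

#' Overwrite a generator state's weights from a flat vector
#' @param state a `generator_state`.
#' @param v numeric vector of the exact length of [get_weights()].
#' @return the state, invisibly (modified in place).
#' @export
set_weights <- function(state, v) {
  np <- length(flatten_params(state$params))
  nb <- length(flatten_params(state$buffers))
  if (length(v) != np + nb)
    stop("weight vector length ", length(v), " != expected ", np + nb)
  state$params <- unflatten_params(state$params, v[seq_len(np)])
  if (nb > 0)
    state$buffers <- unflatten_params(state$buffers, v[np + seq_len(nb)])
  invisible(state)
}

# Deep copy of a generator state (environments are reference semantics).
copy_state <- function(state) {
  st <- new.env(parent = emptyenv())
  for (nm in ls(state, all.names = TRUE)) assign(nm, get(nm, state), st)
  class(st) <- class(state)
  st
}

#' Train a generator state on a table
#'
#' Dispatches to the model kind's training routine. Training continues the
#' state's own RNG/optimizer streams, so `train_model(st, t, e1)` followed
#' by `train_model(st, t, e2)` is identical to one call with `e1 + e2`
#' epochs.
#'
#' @param state a `generator_state` (modified in place and returned).
#' @param table training `clinical_table`.
#' @param epochs number of passes; `< 1` is a warning no-op.
#' @return the trained state.
#' @export
train_model <- function(state, table, epochs = state$config$epochs) {
  if (epochs < 1) {
    warning("epochs < 1: training skipped")
    return(state)
  }
  switch(state$kind,
         ctgan = train_ctgan(state, table, epochs),
         diffusion = train_diffusion(state, table, epochs),
         resampler = {
           state$train_rows <- table
           state
         })
}

#' Sample a synthetic table from a generator state
#'
#' @param state a trained or freshly initialised `generator_state`.
#' @param m number of records.
#' @param seed integer seed; sampling is deterministic given
#'   `(state, m, seed)` and does not consume the state's training RNG.
#' @return a [clinical_table()] of `m` schema-valid records.
#' @export
sample_synthetic <- function(state, m, seed = 1) {
  stopifnot(m >= 1)
  switch(state$kind,
         ctgan = sample_ctgan(state, m, seed),
         diffusion = sample_diffusion(state, m, seed),
         resampler = {
           tab <- state$train_rows
           if (is.null(tab)) stop("resampler state has no training table")
           idx <- with_seed(seed, sample.int(nrow(tab$data), m, replace = TRUE))
           ct_subset(tab, idx)
         })
}
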