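# Minimal dense-network machinery for the two generative models: 2-hidden-
# layer MLPs with manual forward/backward passes over BLAS matrix ops, and
# an Adam optimizer with optional L2 weight decay. Parameters live in plain
# named lists so federated averaging can view them as one flat vector.

glorot_init <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}

#' @keywords internal
mlp3_init <- function(d_in, h1, h2, d_out) {
  list(W1 = glorot_init(d_in, h1), b1 = rep(0, h1),
       W2 = glorot_init(h1, h2),   b2 = rep(0, h2),
       W3 = glorot_init(h2, d_out), b3 = rep(0, d_out))
}

add_bias <- function(M, b) M + matrix(b, nrow(M), length(b), byrow = TRUE)

# per-column scale/shift: M * s + t (column-major recycling avoided)
col_affine <- function(M, s, t) {
  n <- nrow(M); k <- length(s)
  M * matrix(s, n, k, byrow = TRUE) + matrix(t, n, k, byrow = TRUE)
}

# Derivative mask of ReLU / leaky-ReLU, reused by forward and backward.
act_mask <- function(A, act, slope = 0.2) {
  if (act == "relu") (A > 0) * 1 else (A > 0) + slope * (A <= 0)
}

# Forward pass; caches activation masks for the backward pass.
mlp3_forward <- function(p, X, act = "relu") {
  A1 <- add_bias(X %*% p$W1, p$b1)
  M1 <- act_mask(A1, act)
  H1 <- A1 * M1
  A2 <- add_bias(H1 %*% p$W2, p$b2)
  M2 <- act_mask(A2, act)
  H2 <- A2 * M2
  out <- add_bias(H2 %*% p$W3, p$b3)
  list(out = out, X = X, H1 = H1, H2 = H2, M1 = M1, M2 = M2)
}

# Backward pass from dOut (gradient of the loss w.r.t. the output rows).
# Returns parameter gradients and the gradient w.r.t. the input matrix.
mlp3_backward <- function(p, cache, dOut) {
  dA2 <- tcrossprod(dOut, p$W3) * cache$M2
  dA1 <- tcrossprod(dA2, p$W2) * cache$M1
  list(grads = list(W1 = crossprod(cache$X, dA1), b1 = colSums(dA1),
                    W2 = crossprod(cache$H1, dA2), b2 = colSums(dA2),
                    W3 = crossprod(cache$H2, dOut), b3 = colSums(dOut)),
       dX = tcrossprod(dA1, p$W1))
}

# Gradient of the network output (summed over the scalar output) w.r.t. its
# input, per row — used by the WGAN gradient penalty (output dim must be 1).
mlp3_input_grad <- function(p, cache) {
  U2 <- cache$M2 * rep(p$W3[, 1], each = nrow(cache$M2))
  U1 <- cache$M1 * tcrossprod(U2, p$W2)
  list(G = tcrossprod(U1, p$W1), U1 = U1, U2 = U2)
}

# Parameter gradients of the two-sided gradient penalty
# lambda * mean_i (||g_i|| - 1)^2 at fixed activation masks (exact almost
# everywhere for piecewise-linear activations). `ig` is mlp3_input_grad().
gp_param_grads <- function(p, cache, ig, lambda) {
  n <- nrow(ig$G)
  r <- sqrt(rowSums(ig$G^2)) + 1e-12
  cc <- 2 * lambda * (r - 1) / r / n
  Gc <- ig$G * cc
  V <- cache$M1 * (Gc %*% p$W1)       # n x h1
  list(W1 = crossprod(Gc, ig$U1),
       b1 = rep(0, length(p$b1)),
       W2 = crossprod(V, ig$U2),
       b2 = rep(0, length(p$b2)),
       W3 = matrix(colSums(cache$M2 * (V %*% p$W2)), ncol = 1),
       b3 = 0)
}

gp_penalty_value <- function(ig, lambda) {
  r <- sqrt(rowSums(ig$G^2))
  lambda * mean((r - 1)^2)
}

adam_init <- function(params) {
  list(m = lapply(params, function(w) w * 0),
       v = lapply(params, function(w) w * 0),
       t = 0)
}

# One Adam step; `wd` is L2 weight decay folded into the gradient (the
# convention of the reference GAN implementation). Returns updated
# (params, opt).
adam_step <- function(params, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, wd = 0) {
  opt$t <- opt$t + 1
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (wd > 0) g <- g + wd * params[[nm]]
    m <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    v <- beta2 * opt$v[[nm]] + (1 - beta2) * g^2
    opt$m[[nm]] <- m
    opt$v[[nm]] <- v
    params[[nm]] <- params[[nm]] - (lr / bc1) * m / (sqrt(v / bc2) + eps)
  }
  list(params = params, opt = opt)
}

# -- batch normalization ------------------------------------------------------

bn_init <- function(k) list(gamma = rep(1, k), beta = rep(0, k))
bn_buffers_init <- function(k) list(mean = rep(0, k), var = rep(1, k))

# Training-mode batch norm over rows; updates running buffers (momentum as
# in the reference implementation) and caches batch statistics.
bn_forward_train <- function(A, gamma, beta, buf, momentum = 0.1, eps = 1e-5) {
  n <- nrow(A)
  mu <- colMeans(A)
  va <- colMeans(A^2) - mu^2
  inv <- 1 / sqrt(va + eps)
  Xh <- col_affine(A, inv, -mu * inv)
  buf$mean <- (1 - momentum) * buf$mean + momentum * mu
  buf$var <- (1 - momentum) * buf$var + momentum * va * n / max(n - 1, 1)
  list(out = col_affine(Xh, gamma, beta), Xh = Xh, inv = inv, buf = buf)
}

bn_forward_eval <- function(A, gamma, beta, buf, eps = 1e-5) {
  s <- gamma / sqrt(buf$var + eps)
  col_affine(A, s, beta - buf$mean * s)
}

bn_backward <- function(dY, cache, gamma) {
  n <- nrow(dY)
  dgamma <- colSums(dY * cache$Xh)
  dbeta <- colSums(dY)
  dX <- col_affine(dY - col_affine(cache$Xh, dgamma / n, dbeta / n),
                   gamma * cache$inv, rep(0, length(gamma)))
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

# -- generator network: FC -> BN -> ReLU twice, then a linear head ------------

gnet_init <- function(d_in, h1, h2, d_out) {
  list(W1 = glorot_init(d_in, h1), g1 = rep(1, h1), be1 = rep(0, h1),
       W2 = glorot_init(h1, h2),   g2 = rep(1, h2), be2 = rep(0, h2),
       W3 = glorot_init(h2, d_out), b3 = rep(0, d_out))
}

gnet_buffers_init <- function(h1, h2) {
  list(m1 = rep(0, h1), v1 = rep(1, h1), m2 = rep(0, h2), v2 = rep(1, h2))
}

gnet_forward_train <- function(p, buf, X) {
  A1 <- X %*% p$W1
  bn1 <- bn_forward_train(A1, p$g1, p$be1, list(mean = buf$m1, var = buf$v1))
  M1 <- (bn1$out > 0) * 1
  H1 <- bn1$out * M1
  A2 <- H1 %*% p$W2
  bn2 <- bn_forward_train(A2, p$g2, p$be2, list(mean = buf$m2, var = buf$v2))
  M2 <- (bn2$out > 0) * 1
  H2 <- bn2$out * M2
  out <- add_bias(H2 %*% p$W3, p$b3)
  list(out = out, X = X, bn1 = bn1, M1 = M1, H1 = H1,
       bn2 = bn2, M2 = M2, H2 = H2,
       buf = list(m1 = bn1$buf$mean, v1 = bn1$buf$var,
                  m2 = bn2$buf$mean, v2 = bn2$buf$var))
}

gnet_forward_eval <- function(p, buf, X) {
  H1 <- bn_forward_eval(X %*% p$W1, p$g1, p$be1,
                        list(mean = buf$m1, var = buf$v1))
  H1 <- pmax(H1, 0)
  H2 <- bn_forward_eval(H1 %*% p$W2, p$g2, p$be2,
                        list(mean = buf$m2, var = buf$v2))
  H2 <- pmax(H2, 0)
  add_bias(H2 %*% p$W3, p$b3)
}

gnet_backward <- function(p, cache, dOut) {
  dH2 <- tcrossprod(dOut, p$W3) * cache$M2
  b2 <- bn_backward(dH2, cache$bn2, p$g2)
  dH1 <- tcrossprod(b2$dX, p$W2) * cache$M1
  b1 <- bn_backward(dH1, cache$bn1, p$g1)
  list(W1 = crossprod(cache$X, b1$dX), g1 = b1$dgamma, be1 = b1$dbeta,
       W2 = crossprod(cache$H1, b2$dX), g2 = b2$dgamma, be2 = b2$dbeta,
       W3 = crossprod(cache$H2, dOut), b3 = colSums(dOut))
}

# -- discriminator with dropout ----------------------------------------------

# Leaky-ReLU MLP with inverted dropout after each hidden activation
# (training mode draws fresh masks; eval mode runs plain). The dropout
# masks fold into the activation masks, so the gradient-penalty algebra is
# unchanged.
dnet_forward <- function(p, X, train = TRUE, drop = 0.5, slope = 0.2) {
  A1 <- add_bias(X %*% p$W1, p$b1)
  M1 <- act_mask(A1, "leaky", slope)
  if (train && drop > 0)
    M1 <- M1 * (matrix(stats::runif(length(A1)), nrow(A1)) > drop) / (1 - drop)
  H1 <- A1 * M1
  A2 <- add_bias(H1 %*% p$W2, p$b2)
  M2 <- act_mask(A2, "leaky", slope)
  if (train && drop > 0)
    M2 <- M2 * (matrix(stats::runif(length(A2)), nrow(A2)) > drop) / (1 - drop)
  H2 <- A2 * M2
  out <- add_bias(H2 %*% p$W3, p$b3)
  list(out = out, X = X, H1 = H1, H2 = H2, M1 = M1, M2 = M2)
}

flatten_params <- function(params) as.numeric(unlist(params, use.names = FALSE))

unflatten_params <- function(template, v) {
  out <- template
  pos <- 0
  for (nm in names(template)) {
    k <- length(template[[nm]])
    w <- v[pos + seq_len(k)]
    if (is.matrix(template[[nm]]))
      w <- matrix(w, nrow(template[[nm]]), ncol(template[[nm]]))
    out[[nm]] <- w
    pos <- pos + k
  }
  out
}
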