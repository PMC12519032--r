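# Global encoding of a mixed-type table into the continuous representation
# the generative models train on: one-hot blocks for categorical columns and
# mode-specific normalization for continuous ones (a Gaussian mixture fitted
# per column; each value carries a normalized scalar plus a one-hot mode
# indicator). The transformer is fitted ONCE on the full table before any
# client partitioning and shared by every federated node, so all clients see
# the same mapping and no node encounters unseen classes.

#' Fit the global table transformer
#'
#' Continuous columns get a univariate Gaussian mixture (unequal variances,
#' number of components chosen by BIC up to `max_modes`, then components
#' with weight < 0.005 pruned and weights renormalised). Categorical columns
#' get an ordered label-to-position one-hot map covering the schema's label
#' set. A constant continuous column degenerates to a single mode with floor
#' scale 1e-6 rather than failing.
#'
#' @param table a [clinical_table()].
#' @param max_modes maximum mixture components per continuous column.
#' @return a `transformer` object with per-column encoders and the encoded
#'   layout (block offsets and widths).
#' @export
fit_transformer <- function(table, max_modes = 10) {
  stopifnot(nrow(table$data) > 0, max_modes >= 1)
  schema <- table$schema
  enc <- list()
  for (cs in schema$columns) {
    v <- table$data[[cs$name]]
    if (cs$kind == "categorical") {
      enc[[cs$name]] <- list(type = "onehot", levels = cs$levels,
                             width = length(cs$levels))
    } else {
      enc[[cs$name]] <- c(fit_column_mixture(v, max_modes), type = "gmm")
    }
  }
  layout <- list(); off <- 0L
  for (cs in schema$columns) {
    e <- enc[[cs$name]]
    w <- if (e$type == "gmm") 1L + length(e$means) else e$width
    layout[[cs$name]] <- list(type = e$type, offset = off, width = w)
    off <- off + w
  }
  structure(list(columns = schema_names(schema), encoders = enc,
                 layout = layout, width = off, schema = schema),
            class = "transformer")
}

# BIC-selected 1-D Gaussian mixture, components under the weight threshold
# pruned, modes sorted by mean for a stable block order.
fit_column_mixture <- function(v, max_modes, prune = 0.005, sd_floor = 1e-6) {
  if (length(unique(v)) < 2) {
    return(list(weights = 1, means = v[1], sds = sd_floor))
  }
  mclustBIC <- mclust::mclustBIC   # Mclust resolves this in the caller
  fit <- mclust::Mclust(v, G = seq_len(max_modes),
                        modelNames = c("E", "V"), verbose = FALSE)
  w <- as.numeric(fit$parameters$pro)
  mu <- as.numeric(fit$parameters$mean)
  sig <- sqrt(as.numeric(fit$parameters$variance$sigmasq))
  if (length(sig) == 1) sig <- rep(sig, length(mu))
  keep <- w >= prune
  if (!any(keep)) keep <- which.max(w)
  w <- w[keep] / sum(w[keep]); mu <- mu[keep]; sig <- pmax(sig[keep], sd_floor)
  ord <- order(mu)
  list(weights = w[ord], means = mu[ord], sds = sig[ord])
}

#' Width of the encoded representation
#' @param tr a `transformer`.
#' @return integer total encoded width.
#' @export
encoded_width <- function(tr) tr$width

# Responsibilities of each mode for values v (n x K), guarded against
# all-zero rows far in the tails.
mode_responsibilities <- function(e, v) {
  K <- length(e$means)
  R <- vapply(seq_len(K), function(k)
    e$weights[k] * stats::dnorm(v, e$means[k], e$sds[k]), numeric(length(v)))
  R <- matrix(R, nrow = length(v))
  rs <- rowSums(R)
  bad <- rs <= 0 | !is.finite(rs)
  if (any(bad)) {
    # fall back to nearest-mean assignment in the extreme tails
    nearest <- apply(abs(outer(v[bad], e$means, "-")), 1, which.min)
    R[bad, ] <- 0
    R[cbind(which(bad), nearest)] <- 1
    rs[bad] <- 1
  }
  R / rs
}

#' Encode a clinical table
#'
#' Continuous value `v` is normalised against one sampled mixture mode `k*`
#' (sampled with probability proportional to the mode responsibilities, or
#' the argmax mode under `deterministic_modes`): `alpha = (v - mu_k) / (4
#' sd_k)` clipped to `[-1, 1]`, plus a one-hot indicator of `k*`. Categorical
#' codes become one-hot blocks.
#'
#' @param table a `clinical_table` with the transformer's column order.
#' @param tr a fitted `transformer`.
#' @param seed optional seed for mode sampling; `NULL` uses the current RNG.
#' @param deterministic_modes if `TRUE`, pick the most responsible mode
#'   instead of sampling (exact reproducibility without a seed).
#' @return an `encoded_table`: list with the numeric matrix `X` and `layout`.
#' @export
transform_table <- function(table, tr, seed = NULL, deterministic_modes = FALSE) {
  if (!identical(schema_names(table$schema), tr$columns))
    stop("table columns do not match the transformer's column order")
  n <- nrow(table$data)
  X <- matrix(0, n, tr$width)
  body <- function() {
    for (nm in tr$columns) {
      e <- tr$encoders[[nm]]; lay <- tr$layout[[nm]]
      v <- table$data[[nm]]
      if (e$type == "onehot") {
        if (min(v) < 1 || max(v) > length(e$levels))
          stop("unseen label code in column '", nm, "': ",
               paste(setdiff(unique(v), seq_along(e$levels)), collapse = ", "))
        X[cbind(seq_len(n), lay$offset + v)] <<- 1
      } else {
        K <- length(e$means)
        R <- mode_responsibilities(e, v)
        ks <- if (deterministic_modes || K == 1) {
          max.col(R, ties.method = "first")
        } else {
          u <- stats::runif(n)
          rowSums(u > t(apply(R, 1, cumsum))) + 1L
        }
        ks <- pmin(ks, K)
        alpha <- (v - e$means[ks]) / (4 * e$sds[ks])
        X[, lay$offset + 1L] <<- pmin(1, pmax(-1, alpha))
        X[cbind(seq_len(n), lay$offset + 1L + ks)] <<- 1
      }
    }
  }
  if (is.null(seed)) body() else with_seed(seed, body())
  structure(list(X = X, layout = tr$layout, width = tr$width),
            class = "encoded_table")
}

#' Decode an encoded table back to table space
#'
#' Mode and categorical blocks are resolved by argmax (deterministic
#' tie-break: lowest index); continuous values are reconstructed as
#' `alpha * 4 sd_k + mu_k` and clipped to the schema range so any model
#' output decodes to a schema-valid table. An all-zero block therefore
#' resolves to its first position.
#'
#' @param enc an `encoded_table` (or bare numeric matrix of matching width).
#' @param tr the `transformer` used to encode.
#' @return a [clinical_table()].
#' @export
inverse_transform <- function(enc, tr) {
  X <- if (is.matrix(enc)) enc else enc$X
  if (ncol(X) != tr$width)
    stop("encoded width ", ncol(X), " does not match transformer width ", tr$width)
  n <- nrow(X)
  out <- list()
  for (nm in tr$columns) {
    e <- tr$encoders[[nm]]; lay <- tr$layout[[nm]]
    if (e$type == "onehot") {
      block <- X[, lay$offset + seq_len(lay$width), drop = FALSE]
      out[[nm]] <- max.col(block, ties.method = "first")
    } else {
      K <- length(e$means)
      alpha <- pmin(1, pmax(-1, X[, lay$offset + 1L]))
      block <- X[, lay$offset + 1L + seq_len(K), drop = FALSE]
      ks <- max.col(block, ties.method = "first")
      v <- alpha * 4 * e$sds[ks] + e$means[ks]
      cs <- schema_col(tr$schema, nm)
      out[[nm]] <- pmin(cs$range[2], pmax(cs$range[1], v))
    }
  }
  names(out) <- tr$columns
  clinical_table(tr$schema, as.data.frame(out))
}

#' Serialize a transformer to JSON
#' @param tr a `transformer`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_transformer <- function(tr, path) {
  js <- list(columns = tr$columns,
             encoders = tr$encoders,
             width = tr$width)
  jsonlite::write_json(js, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a transformer written by [write_transformer()]
#'
#' @param path file path.
#' @param schema the [table_schema()] the transformer was fitted for (the
#'   JSON stores encoders and layout, not the schema itself).
#' @return a `transformer`.
#' @export
read_transformer <- function(path, schema) {
  js <- jsonlite::read_json(path, simplifyVector = FALSE)
  enc <- lapply(js$encoders, function(e) {
    if (identical(e$type, "onehot")) {
      list(type = "onehot", levels = as.character(unlist(e$levels)),
           width = as.integer(e$width))
    } else {
      list(weights = as.numeric(unlist(e$weights)),
           means = as.numeric(unlist(e$means)),
           sds = as.numeric(unlist(e$sds)), type = "gmm")
    }
  })
  names(enc) <- unlist(js$columns)
  layout <- list(); off <- 0L
  for (nm in names(enc)) {
    e <- enc[[nm]]
    w <- if (e$type == "gmm") 1L + length(e$means) else e$width
    layout[[nm]] <- list(type = e$type, offset = off, width = w)
    off <- off + w
  }
  stopifnot(off == js$width)
  structure(list(columns = unlist(js$columns), encoders = enc,
                 layout = layout, width = off, schema = schema),
            class = "transformer")
}
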