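# Fidelity battery comparing a synthetic table against the real one:
# phi-k correlation matrices compared by cosine similarity, the Vendi
# diversity score, per-column Hellinger distances, a depth-depth plot R
# squared and a detection (data labeling) analysis.

# -- phi-k --------------------------------------------------------------------

# Gauss-Legendre nodes/weights on [-1, 1] via the Golub-Welsch eigenvalue
# recurrence (no quadrature package in the dependency set).
gauss_legendre <- function(n) {
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  list(nodes = rev(e$values), weights = rev(2 * e$vectors[1, ]^2))
}

# Expected bivariate-normal cell probabilities for bin edges xe, ye at
# correlation rho, by quadrature over the outer variable.
bvn_cell_probs <- function(xe, ye, rho, gl) {
  r <- length(xe) - 1; cidx <- length(ye) - 1
  s <- sqrt(max(1 - rho^2, 1e-12))
  P <- matrix(0, r, cidx)
  for (i in seq_len(r)) {
    a <- xe[i]; b <- xe[i + 1]
    x <- (a + b) / 2 + (b - a) / 2 * gl$nodes
    w <- (b - a) / 2 * gl$weights * stats::dnorm(x)
    Fy <- vapply(ye, function(y) stats::pnorm((y - rho * x) / s),
                 numeric(length(x)))
    P[i, ] <- colSums(w * (Fy[, -1, drop = FALSE] - Fy[, -(cidx + 1), drop = FALSE]))
  }
  P
}

# phi-k of a contingency table: the correlation of a binned bivariate
# normal whose expected chi-square (with the (r-1)(c-1) sample-noise
# pedestal subtracted from the observed statistic) matches the observed one.
phik_from_contingency <- function(tab, tol = 1e-6) {
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  r <- nrow(tab); cc <- ncol(tab)
  if (r < 2 || cc < 2) return(0)
  n <- sum(tab)
  p <- rowSums(tab) / n
  q <- colSums(tab) / n
  E <- n * outer(p, q)
  chi2 <- sum((tab - E)^2 / E)
  chi2c <- max(0, chi2 - (r - 1) * (cc - 1))
  if (chi2c <= 0) return(0)
  gl <- gauss_legendre(24)
  lim <- 8
  xe <- pmin(lim, pmax(-lim, stats::qnorm(c(0, cumsum(p)))))
  ye <- pmin(lim, pmax(-lim, stats::qnorm(c(0, cumsum(q)))))
  chi2_th <- function(rho) {
    P <- bvn_cell_probs(xe, ye, rho, gl)
    n * sum((P - outer(p, q))^2 / outer(p, q))
  }
  hi <- 0.999
  if (chi2_th(hi) <= chi2c) return(1)
  stats::uniroot(function(rho) chi2_th(rho) - chi2c, c(0, hi), tol = tol)$root
}

#' Pairwise phi-k correlation matrix of a mixed-type table
#'
#' Continuous columns are discretised into `n_bins` equal-frequency bins;
#' each pair's contingency table yields a Pearson chi-square which, after
#' subtraction of the independence noise pedestal, is inverted to the
#' correlation of a binned bivariate normal. Values lie in `[0, 1]`; a
#' column with a single distinct value correlates 0 with everything.
#'
#' @param table a [clinical_table()].
#' @param n_bins equal-frequency bins for continuous columns (default 10).
#' @return symmetric p x p matrix with unit diagonal.
#' @export
phik_matrix <- function(table, n_bins = 10) {
  stopifnot(nrow(table$data) >= 2)
  schema <- table$schema
  nms <- schema_names(schema)
  disc <- lapply(schema$columns, function(cs) {
    v <- table$data[[cs$name]]
    if (cs$kind == "categorical") return(factor(v, seq_along(cs$levels)))
    br <- unique(stats::quantile(v, seq(0, 1, length.out = n_bins + 1)))
    if (length(br) < 3) return(factor(rep(1, length(v))))
    cut(v, br, include.lowest = TRUE)
  })
  p <- length(nms)
  M <- diag(p)
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      M[i, j] <- M[j, i] <- phik_from_contingency(table(disc[[i]], disc[[j]]))
    }
  }
  dimnames(M) <- list(nms, nms)
  M
}

#' Cosine similarity between two correlation matrices
#'
#' Flattens the strict upper triangles (the unit diagonal carries no
#' information and would inflate similarity) and returns
#' `1 - d_cos = <x, y> / (||x|| ||y||)`. If both vectors are zero the
#' matrices agree trivially and the score is 1; if only one is zero, 0.
#'
#' @param A,B same-shape correlation matrices with matching column order.
#' @param upper_only compare strict upper triangles (default) or the full
#'   flattened matrices.
#' @return similarity score in `[-1, 1]`.
#' @export
matrix_cosine_similarity <- function(A, B, upper_only = TRUE) {
  if (!all(dim(A) == dim(B))) stop("matrix shapes differ")
  x <- if (upper_only) A[upper.tri(A)] else as.numeric(A)
  y <- if (upper_only) B[upper.tri(B)] else as.numeric(B)
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 && ny == 0) return(1)
  if (nx == 0 || ny == 0) return(0)
  sum(x * y) / (nx * ny)
}

#' Vendi diversity score of a table's numeric block
#'
#' Cosine-similarity kernel over z-scored continuous columns; the score is
#' `exp` of the Shannon entropy of the eigenvalues of `K/n`, between 1
#' (all rows identical up to scale) and `n` (orthogonal rows). The nonzero
#' eigenvalues of `K/n` are computed from the d x d Gram matrix of the
#' row-normalised data, so cost does not grow quadratically in `n`.
#'
#' @param table a [clinical_table()] with at least one continuous column.
#' @return the Vendi score.
#' @export
vendi_score <- function(table) {
  cc <- continuous_cols(table$schema)
  if (length(cc) == 0) stop("no continuous columns for the Vendi kernel")
  X <- as.matrix(table$data[cc])
  sds <- apply(X, 2, stats::sd)
  keep <- sds > 0
  X[, keep] <- scale(X[, keep, drop = FALSE])  # zero-variance columns stay raw
  vendi_kernel_score(X)
}

# Vendi score of the cosine-similarity kernel over the rows of a numeric
# matrix: exp of the Shannon entropy of the eigenvalues of K/n.
vendi_kernel_score <- function(X) {
  nrm <- sqrt(rowSums(X^2))
  if (any(nrm == 0)) {
    warning(sum(nrm == 0), " zero-norm rows excluded from the Vendi kernel")
    X <- X[nrm > 0, , drop = FALSE]
    nrm <- nrm[nrm > 0]
  }
  n <- nrow(X)
  Xu <- X / nrm
  lam <- eigen(crossprod(Xu) / n, symmetric = TRUE, only.values = TRUE)$values
  if (min(lam) < -1e-8) stop("similarity kernel has negative eigenvalues")
  lam <- pmax(lam, 0)
  lam <- lam[lam > 0]
  exp(-sum(lam * log(lam)))
}

#' Hellinger distance between two columns
#'
#' Categorical columns: `sqrt(1 - sum(sqrt(p q)))` over the union of
#' labels. Continuous columns: the same formula over `n_bins` equal-width
#' bins spanning the pooled range.
#'
#' @param real_col,syn_col numeric vectors of the same kind.
#' @param kind `"continuous"` or `"categorical"`.
#' @param n_bins equal-width bins for continuous columns (default 20).
#' @return distance in `[0, 1]`.
#' @export
hellinger_distance <- function(real_col, syn_col, kind, n_bins = 20) {
  if (length(real_col) == 0 || length(syn_col) == 0) stop("empty column")
  if (kind == "categorical") {
    lev <- sort(unique(c(real_col, syn_col)))
    p <- tabulate(match(real_col, lev), length(lev)) / length(real_col)
    q <- tabulate(match(syn_col, lev), length(lev)) / length(syn_col)
  } else {
    rng <- range(c(real_col, syn_col))
    if (rng[1] == rng[2]) return(0)
    br <- seq(rng[1], rng[2], length.out = n_bins + 1)
    p <- tabulate(findInterval(real_col, br, rightmost.closed = TRUE), n_bins) /
      length(real_col)
    q <- tabulate(findInterval(syn_col, br, rightmost.closed = TRUE), n_bins) /
      length(syn_col)
  }
  sqrt(max(0, 1 - sum(sqrt(p * q))))
}

#' Mean Hellinger distance over all schema columns
#'
#' @param real,syn `clinical_table`s over the same schema.
#' @param n_bins bins for continuous columns.
#' @return average of the per-column distances.
#' @export
mean_hellinger <- function(real, syn, n_bins = 20) {
  mean(vapply(real$schema$columns, function(cs)
    hellinger_distance(real$data[[cs$name]], syn$data[[cs$name]],
                       cs$kind, n_bins), 0))
}

# Mahalanobis depth of rows `Z` with respect to sample `S` (ridge on the
# covariance for numerical safety).
mahalanobis_depth <- function(Z, S, ridge = 1e-6) {
  mu <- colMeans(S)
  Sig <- stats::cov(S) + diag(ridge, ncol(S))
  Si <- tryCatch(solve(Sig),
                 error = function(e) stop("singular covariance in depth"))
  d2 <- stats::mahalanobis(Z, mu, Si, inverted = TRUE)
  1 / (1 + d2)
}

#' Depth-depth plot R squared
#'
#' Mahalanobis depths of the pooled continuous rows with respect to the
#' real and the synthetic sample; agreement is the coefficient of
#' determination against the theoretical identity line `x = y` (not a
#' fitted line), floored at 0.
#'
#' @param real,syn `clinical_table`s over the same schema.
#' @return R squared in `[0, 1]`.
#' @export
ddplot_r2 <- function(real, syn) {
  cc <- continuous_cols(real$schema)
  Xr <- as.matrix(real$data[cc]); Xs <- as.matrix(syn$data[cc])
  if (nrow(Xr) < length(cc) + 2 || nrow(Xs) < length(cc) + 2)
    stop("too few rows for depth estimation")
  Z <- rbind(Xr, Xs)
  x <- mahalanobis_depth(Z, Xr)
  y <- mahalanobis_depth(Z, Xs)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) return(if (sum((y - x)^2) == 0) 1 else 0)
  max(0, 1 - sum((y - x)^2) / ss_tot)
}
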