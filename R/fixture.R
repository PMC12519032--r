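# Gaussian-copula fixture generator.
#
# Records are drawn from a Gaussian copula with the schema's rank-correlation
# target: latent MVN draws are transformed to uniforms, then pushed through
# each column's marginal quantile function (truncated normal / log-normal for
# continuous columns; cumulative category probabilities for categoricals).
# Spearman targets are mapped to the latent Pearson scale via
# r = 2 sin(pi * rho / 6), exact for continuous marginals and a close
# approximation for the discretised ones.

marginal_cdf <- function(cs) {
  a <- cs$range[1]; b <- cs$range[2]; pr <- cs$params
  switch(cs$family,
    tnorm = {
      Fa <- stats::pnorm(a, pr[["mean"]], pr[["sd"]])
      Fb <- stats::pnorm(b, pr[["mean"]], pr[["sd"]])
      function(x) (stats::pnorm(x, pr[["mean"]], pr[["sd"]]) - Fa) / (Fb - Fa)
    },
    tlnorm = {
      Fa <- stats::plnorm(a, pr[["meanlog"]], pr[["sdlog"]])
      Fb <- stats::plnorm(b, pr[["meanlog"]], pr[["sdlog"]])
      function(x) (stats::plnorm(x, pr[["meanlog"]], pr[["sdlog"]]) - Fa) / (Fb - Fa)
    },
    stop("unknown continuous family: ", cs$family)
  )
}

marginal_quantile <- function(cs) {
  a <- cs$range[1]; b <- cs$range[2]; pr <- cs$params
  switch(cs$family,
    tnorm = {
      Fa <- stats::pnorm(a, pr[["mean"]], pr[["sd"]])
      Fb <- stats::pnorm(b, pr[["mean"]], pr[["sd"]])
      function(u) pmin(b, pmax(a, stats::qnorm(Fa + u * (Fb - Fa),
                                               pr[["mean"]], pr[["sd"]])))
    },
    tlnorm = {
      Fa <- stats::plnorm(a, pr[["meanlog"]], pr[["sdlog"]])
      Fb <- stats::plnorm(b, pr[["meanlog"]], pr[["sdlog"]])
      function(u) pmin(b, pmax(a, stats::qlnorm(Fa + u * (Fb - Fa),
                                                pr[["meanlog"]], pr[["sdlog"]])))
    },
    stop("unknown continuous family: ", cs$family)
  )
}

#' Draw a synthetic clinical table from a schema
#'
#' @param schema a [table_schema()]; defaults to [build_aml_schema()].
#' @param n number of records; defaults to `schema$n_default`.
#' @param seed integer seed; the draw is deterministic given
#'   `(schema, n, seed)`.
#' @return a [clinical_table()].
#' @export
#' @examples
#' ct <- generate_fixture(seed = 1)
#' dim(ct)
generate_fixture <- function(schema = build_aml_schema(),
                             n = schema$n_default, seed = 1) {
  stopifnot(n >= 1)
  p <- length(schema$columns)
  latent <- 2 * sin(pi * schema$correlation / 6)
  diag(latent) <- 1
  L <- tryCatch(chol(latent),
                error = function(e) stop("correlation target is not positive ",
                                         "definite on the latent scale"))
  U <- with_seed(seed, {
    Z <- matrix(stats::rnorm(n * p), n, p) %*% L
    stats::pnorm(Z)
  })
  out <- vector("list", p)
  for (j in seq_len(p)) {
    cs <- schema$columns[[j]]
    out[[j]] <- if (cs$kind == "continuous") {
      marginal_quantile(cs)(U[, j])
    } else {
      findInterval(U[, j], cumsum(cs$probs), left.open = TRUE) + 1L
    }
  }
  names(out) <- schema_names(schema)
  clinical_table(schema, as.data.frame(out))
}

#' Write a clinical table to CSV with a sidecar JSON schema
#'
#' The CSV holds the label-encoded grid (header row, '.' decimal); the
#' sidecar `<path>.schema.json` carries column specs and the correlation
#' target so the table round-trips.
#'
#' @param ct a `clinical_table`.
#' @param path CSV file path; the schema goes to `paste0(path, ".schema.json")`.
#' @return `path`, invisibly.
#' @export
write_clinical_table <- function(ct, path) {
  utils::write.csv(ct$data, path, row.names = FALSE)
  sch <- ct$schema
  js <- list(
    n_default = sch$n_default,
    correlation = unname(sch$correlation),
    columns = lapply(sch$columns, function(cs) {
      cs <- cs[!vapply(cs, is.null, TRUE)]
      if (!is.null(cs$params)) cs$params <- as.list(cs$params)  # keep names
      cs
    })
  )
  jsonlite::write_json(js, paste0(path, ".schema.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a clinical table written by [write_clinical_table()]
#'
#' @param path CSV file path.
#' @param schema_path sidecar schema path; defaults to
#'   `paste0(path, ".schema.json")`.
#' @return a `clinical_table`.
#' @export
read_clinical_table <- function(path, schema_path = paste0(path, ".schema.json")) {
  js <- jsonlite::read_json(schema_path, simplifyVector = FALSE)
  cols <- lapply(js$columns, function(cl) {
    column_spec(
      name = cl$name, kind = cl$kind, family = cl$family,
      params = if (!is.null(cl$params)) unlist(cl$params),
      range = if (!is.null(cl$range)) as.numeric(unlist(cl$range)),
      levels = if (!is.null(cl$levels)) as.character(unlist(cl$levels)),
      probs = if (!is.null(cl$probs)) as.numeric(unlist(cl$probs)),
      conditioning = isTRUE(cl$conditioning)
    )
  })
  R <- do.call(rbind, lapply(js$correlation, function(r) as.numeric(unlist(r))))
  schema <- table_schema(cols, js$n_default, R)
  dat <- utils::read.csv(path)
  for (nm in categorical_cols(schema)) dat[[nm]] <- as.integer(dat[[nm]])
  clinical_table(schema, dat)
}
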