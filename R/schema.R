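# Schema and clinical-table container for the synthetic AML-like study table.
#
# The study table is emulated, not reproduced: the published cohort's variable
# identities are not public, so the default schema is an explicit stand-in
# with the same shape (1540 records, 12 mixed-type features, an `age` column
# usable for non-IID conditioning, label-encoded categoricals) and a
# documented rank-correlation structure coupling clinically related columns.

#' Column specification for a clinical table schema
#'
#' @param name column name.
#' @param kind `"continuous"` or `"categorical"`.
#' @param family for continuous columns: `"tnorm"` (truncated normal) or
#'   `"tlnorm"` (truncated log-normal).
#' @param params named numeric parameters of the family (`mean`/`sd` or
#'   `meanlog`/`sdlog`).
#' @param range length-2 numeric `c(min, max)` for continuous columns.
#' @param levels character labels for categorical columns.
#' @param probs category probabilities (sum to 1) for categorical columns.
#' @param conditioning logical; `TRUE` for the single column used for
#'   non-IID partition conditioning.
#' @return a `column_spec` object.
#' @export
column_spec <- function(name, kind, family = NULL, params = NULL, range = NULL,
                        levels = NULL, probs = NULL, conditioning = FALSE) {
  kind <- match.arg(kind, c("continuous", "categorical"))
  if (kind == "continuous") {
    stopifnot(is.numeric(range), length(range) == 2)
    if (range[1] >= range[2]) stop("continuous column '", name, "': min must be < max")
  } else {
    stopifnot(length(levels) >= 2, length(levels) == length(probs))
    if (abs(sum(probs) - 1) > 1e-9)
      stop("categorical column '", name, "': probabilities must sum to 1")
  }
  structure(list(name = name, kind = kind, family = family, params = params,
                 range = range, levels = levels, probs = probs,
                 conditioning = isTRUE(conditioning)),
            class = "column_spec")
}

#' Table schema: ordered columns plus a copula correlation target
#'
#' @param columns list of [column_spec()] objects.
#' @param n_default default record count.
#' @param correlation target Spearman rank-correlation matrix among columns
#'   (symmetric, unit diagonal, positive semidefinite).
#' @return a `table_schema` object.
#' @export
table_schema <- function(columns, n_default, correlation) {
  p <- length(columns)
  nm <- vapply(columns, `[[`, "", "name")
  stopifnot(nrow(correlation) == p, ncol(correlation) == p)
  if (max(abs(correlation - t(correlation))) > 1e-12)
    stop("correlation matrix must be symmetric")
  if (max(abs(diag(correlation) - 1)) > 1e-12)
    stop("correlation matrix must have unit diagonal")
  if (min(eigen(correlation, symmetric = TRUE, only.values = TRUE)$values) < -1e-10)
    stop("correlation matrix must be positive semidefinite")
  if (sum(vapply(columns, function(cs) cs$conditioning, TRUE)) != 1)
    stop("exactly one column must be flagged as the conditioning column")
  dimnames(correlation) <- list(nm, nm)
  structure(list(columns = columns, n_default = n_default,
                 correlation = correlation),
            class = "table_schema")
}

#' Default 12-column AML-like schema
#'
#' A fixed, documented emulation of an adult AML clinical table: `age` plus
#' four lab/disease continuous measurements (white-cell count, haemoglobin,
#' platelets, marrow blast percentage) and seven categorical
#' clinical/demographic features with 2-5 levels. Correlations couple
#' clinically related pairs (e.g. age with performance status and transplant,
#' white-cell count with blast percentage, cytogenetic risk with response).
#' Spearman targets are mapped to the latent Gaussian scale inside
#' [generate_fixture()].
#'
#' @return a [table_schema()] with 12 columns and `n_default = 1540`.
#' @export
build_aml_schema <- function() {
  cols <- list(
    column_spec("age", "continuous", "tnorm",
                c(mean = 55, sd = 16), range = c(18, 90), conditioning = TRUE),
    column_spec("wbc", "continuous", "tlnorm",
                c(meanlog = log(10), sdlog = 1.1), range = c(0.3, 400)),
    column_spec("hb", "continuous", "tnorm",
                c(mean = 9.6, sd = 1.7), range = c(4, 16)),
    column_spec("platelets", "continuous", "tlnorm",
                c(meanlog = log(60), sdlog = 0.9), range = c(5, 1000)),
    column_spec("bm_blast_pct", "continuous", "tnorm",
                c(mean = 55, sd = 25), range = c(0, 100)),
    column_spec("sex", "categorical", levels = c("F", "M"),
                probs = c(0.46, 0.54)),
    column_spec("ecog", "categorical", levels = c("0", "1", "2", "3"),
                probs = c(0.35, 0.40, 0.17, 0.08)),
    column_spec("aml_type", "categorical", levels = c("de_novo", "secondary"),
                probs = c(0.78, 0.22)),
    column_spec("cyto_risk", "categorical",
                levels = c("favorable", "intermediate", "adverse"),
                probs = c(0.20, 0.55, 0.25)),
    column_spec("who_class", "categorical",
                levels = c("class1", "class2", "class3", "class4", "class5"),
                probs = c(0.30, 0.25, 0.20, 0.15, 0.10)),
    column_spec("transplant", "categorical", levels = c("no", "yes"),
                probs = c(0.65, 0.35)),
    column_spec("cr_response", "categorical", levels = c("CR", "no_CR"),
                probs = c(0.60, 0.40))
  )
  nm <- vapply(cols, `[[`, "", "name")
  R <- diag(12)
  dimnames(R) <- list(nm, nm)
  set_r <- function(a, b, v) {
    R[a, b] <<- v
    R[b, a] <<- v
  }
  set_r("age", "ecog", 0.35)
  set_r("age", "cyto_risk", 0.20)
  set_r("age", "transplant", -0.35)
  set_r("age", "hb", -0.10)
  set_r("wbc", "bm_blast_pct", 0.45)
  set_r("wbc", "hb", -0.15)
  set_r("hb", "platelets", 0.25)
  set_r("bm_blast_pct", "cr_response", -0.25)
  set_r("cyto_risk", "cr_response", -0.30)
  set_r("ecog", "cr_response", -0.20)
  table_schema(cols, n_default = 1540, correlation = R)
}

schema_names <- function(schema) vapply(schema$columns, `[[`, "", "name")
schema_kinds <- function(schema) vapply(schema$columns, `[[`, "", "kind")

#' @export
continuous_cols <- function(schema) schema_names(schema)[schema_kinds(schema) == "continuous"]
#' @export
categorical_cols <- function(schema) schema_names(schema)[schema_kinds(schema) == "categorical"]

schema_col <- function(schema, name) {
  i <- match(name, schema_names(schema))
  if (is.na(i)) stop("unknown column: ", name)
  schema$columns[[i]]
}

#' Clinical table: a schema plus a record grid
#'
#' Continuous cells are numeric; categorical cells are stored as integer
#' codes `1..L` into the schema's label vector (label encoding).
#'
#' @param schema a [table_schema()].
#' @param data a data.frame with columns in schema order.
#' @return a `clinical_table` object.
#' @export
clinical_table <- function(schema, data) {
  stopifnot(identical(names(data), schema_names(schema)))
  ct <- structure(list(schema = schema, data = data), class = "clinical_table")
  validate_clinical_table(ct)
  ct
}

#' Validate clinical-table invariants
#'
#' Checks for missing cells, continuous values outside their declared range
#' and categorical codes outside the label set.
#'
#' @param ct a `clinical_table`.
#' @return `ct`, invisibly; otherwise an error.
#' @export
validate_clinical_table <- function(ct) {
  for (cs in ct$schema$columns) {
    v <- ct$data[[cs$name]]
    if (anyNA(v)) stop("column '", cs$name, "' has missing cells")
    if (cs$kind == "continuous") {
      if (min(v) < cs$range[1] - 1e-9 || max(v) > cs$range[2] + 1e-9)
        stop("column '", cs$name, "' outside range [",
             cs$range[1], ", ", cs$range[2], "]")
    } else {
      if (!all(v == round(v)) || min(v) < 1 || max(v) > length(cs$levels))
        stop("column '", cs$name, "' has codes outside 1..", length(cs$levels))
    }
  }
  invisible(ct)
}

#' @export
print.clinical_table <- function(x, ...) {
  cat("clinical_table:", nrow(x$data), "records x", ncol(x$data), "columns\n")
  cat("  continuous: ", paste(continuous_cols(x$schema), collapse = ", "), "\n")
  cat("  categorical:", paste(categorical_cols(x$schema), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.clinical_table <- function(x) dim(x$data)

#' Subset the rows of a clinical table
#'
#' @param ct a `clinical_table`.
#' @param idx integer row indices.
#' @return a `clinical_table` over the selected rows.
#' @export
ct_subset <- function(ct, idx) {
  structure(list(schema = ct$schema,
                 data = ct$data[idx, , drop = FALSE]),
            class = "clinical_table")
}

#' Map categorical codes back to their labels
#'
#' @param ct a `clinical_table`.
#' @return a data.frame with categorical columns as character labels.
#' @export
decode_labels <- function(ct) {
  out <- ct$data
  for (cs in ct$schema$columns)
    if (cs$kind == "categorical") out[[cs$name]] <- cs$levels[out[[cs$name]]]
  out
}

# Per-column observed range helper used by Gower distance and the attacks.
column_ranges <- function(ct) {
  cc <- continuous_cols(ct$schema)
  vapply(cc, function(nm) {
    cs <- schema_col(ct$schema, nm)
    cs$range[2] - cs$range[1]
  }, 0)
}
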