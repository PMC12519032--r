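# Privacy attacks against a synthetic table, each reported as an excess
# risk over a baseline attacker: membership inference (MIA), attribute
# inference (AIA), linkability and multivariate singling out. Risks are
# normalised as max(0, (success - baseline) / (1 - baseline)), the
# convention of the standard anonymity-evaluation tools.

#' Privacy attack configuration
#'
#' @param gower_threshold MIA match threshold on Gower distance (study
#'   value 0.05).
#' @param aia_tolerance numeric-attribute tolerance as a fraction of the
#'   column range (study value 0.05).
#' @param link_k neighbour count for linkability (default 1).
#' @param n_attacks predicates for singling out (default 500).
#' @return a `privacy_config` list.
#' @export
privacy_config <- function(gower_threshold = 0.05, aia_tolerance = 0.05,
                           link_k = 1, n_attacks = 500) {
  stopifnot(gower_threshold > 0, gower_threshold < 1,
            aia_tolerance > 0, aia_tolerance < 1, link_k >= 1, n_attacks >= 1)
  structure(list(gower_threshold = gower_threshold,
                 aia_tolerance = aia_tolerance,
                 link_k = link_k, n_attacks = n_attacks),
            class = "privacy_config")
}

attack_result <- function(success, baseline, per_column = NULL) {
  risk <- if (baseline >= 1) 0 else max(0, (success - baseline) / (1 - baseline))
  structure(list(success_rate = success, baseline_rate = baseline,
                 risk = min(1, risk), per_column = per_column),
            class = "attack_result")
}

#' @export
print.attack_result <- function(x, ...) {
  cat(sprintf("attack: success %.3f, baseline %.3f, risk %.3f\n",
              x$success_rate, x$baseline_rate, x$risk))
  invisible(x)
}

#' Gower distance between two mixed-type records
#'
#' Mean over columns of the range-normalised absolute difference (numeric,
#' capped at 1) or the mismatch indicator (categorical). A zero-range
#' numeric column contributes 0 when equal, else 1.
#'
#' @param a,b single-row lists/data.frames over the same schema.
#' @param schema the shared [table_schema()].
#' @return distance in `[0, 1]`.
#' @export
gower_distance <- function(a, b, schema) {
  d <- 0
  for (cs in schema$columns) {
    va <- a[[cs$name]]; vb <- b[[cs$name]]
    d <- d + if (cs$kind == "categorical") {
      as.numeric(va != vb)
    } else {
      rg <- cs$range[2] - cs$range[1]
      if (rg <= 0) as.numeric(va != vb) else min(1, abs(va - vb) / rg)
    }
  }
  d / length(schema$columns)
}

# Full Gower cross-distance matrix between the rows of two tables over a
# column subset (default all).
gower_matrix <- function(A, B, cols = NULL) {
  schema <- A$schema
  cols <- cols %||% schema_names(schema)
  n <- nrow(A$data); m <- nrow(B$data)
  D <- matrix(0, n, m)
  for (nm in cols) {
    cs <- schema_col(schema, nm)
    va <- A$data[[nm]]; vb <- B$data[[nm]]
    D <- D + if (cs$kind == "categorical") {
      outer(va, vb, "!=") * 1
    } else {
      rg <- cs$range[2] - cs$range[1]
      if (rg <= 0) outer(va, vb, "!=") * 1
      else pmin(1, abs(outer(va, vb, "-")) / rg)
    }
  }
  D / length(cols)
}

#' Membership inference attack risk
#'
#' A record is claimed a training member when its nearest synthetic
#' neighbour lies within the Gower threshold. The success rate on the
#' training table is compared against the claim rate on a control table
#' drawn from the same generator but never seen by the model.
#'
#' @param train training `clinical_table`.
#' @param control unseen control `clinical_table` of comparable size.
#' @param syn synthetic `clinical_table`.
#' @param cfg a [privacy_config()].
#' @return an `attack_result`.
#' @export
mia_risk <- function(train, control, syn, cfg = privacy_config()) {
  if (nrow(syn$data) == 0) stop("empty synthetic table")
  d_tr <- apply(gower_matrix(train, syn), 1, min)
  d_ct <- apply(gower_matrix(control, syn), 1, min)
  attack_result(mean(d_tr <= cfg$gower_threshold),
                mean(d_ct <= cfg$gower_threshold))
}

#' Attribute inference attack risk
#'
#' Each column in turn is the secret: the attacker finds the synthetic
#' nearest neighbour of every real record on the remaining columns (Gower
#' distance) and predicts the secret from it. Success is an exact match
#' (categorical) or agreement within `aia_tolerance * range` (numeric).
#' The baseline attacker predicts by drawing from the synthetic marginal
#' of the secret column. The overall risk is the mean of the per-column
#' excess risks.
#'
#' @param real,syn `clinical_table`s over the same schema.
#' @param cfg a [privacy_config()].
#' @param seed seed for the baseline marginal draws.
#' @return an `attack_result` with a per-column breakdown.
#' @export
aia_risk <- function(real, syn, cfg = privacy_config(), seed = 1) {
  schema <- real$schema
  nms <- schema_names(schema)
  if (length(nms) < 2) stop("attribute inference needs at least 2 columns")
  if (nrow(real$data) == 0 || nrow(syn$data) == 0) stop("empty table")
  n <- nrow(real$data)
  # per-column distance contributions, summed once; the leave-one-out
  # distance for secret c is (sum - contribution of c) / (p - 1)
  col_d <- lapply(nms, function(nm) gower_matrix(real, syn, cols = nm))
  names(col_d) <- nms
  D_all <- Reduce(`+`, col_d)
  rows <- with_seed(seed, lapply(seq_along(nms), function(ci) {
    nm <- nms[ci]; cs <- schema$columns[[ci]]
    D <- D_all - col_d[[nm]]
    nn <- max.col(-D, ties.method = "first")
    pred <- syn$data[[nm]][nn]
    guess <- syn$data[[nm]][sample.int(nrow(syn$data), n, replace = TRUE)]
    truth <- real$data[[nm]]
    hit <- function(pr) {
      if (cs$kind == "categorical") pr == truth
      else abs(pr - truth) <= cfg$aia_tolerance * (cs$range[2] - cs$range[1])
    }
    succ <- mean(hit(pred)); base <- mean(hit(guess))
    data.frame(column = nm, success = succ, baseline = base,
               risk = attack_result(succ, base)$risk)
  }))
  per_col <- do.call(rbind, rows)
  res <- attack_result(mean(per_col$success), mean(per_col$baseline), per_col)
  res$risk <- mean(per_col$risk)
  res
}

#' Linkability attack risk
#'
#' The attacker holds two disjoint column views of each real record and
#' asks whether the `link_k` nearest synthetic neighbours under view A
#' intersect those under view B. The baseline is the analytic expected
#' intersection of two random `link_k`-subsets of the synthetic table.
#'
#' @param real,syn `clinical_table`s over the same schema.
#' @param colsA,colsB disjoint column sets (default: first half / rest).
#' @param cfg a [privacy_config()].
#' @return an `attack_result`.
#' @export
linkability_risk <- function(real, syn, colsA = NULL, colsB = NULL,
                             cfg = privacy_config()) {
  nms <- schema_names(real$schema)
  half <- length(nms) %/% 2
  colsA <- colsA %||% nms[seq_len(half)]
  colsB <- colsB %||% nms[(half + 1):length(nms)]
  if (length(intersect(colsA, colsB)) > 0) stop("column views must be disjoint")
  k <- cfg$link_k
  m <- nrow(syn$data)
  DA <- gower_matrix(real, syn, cols = colsA)
  DB <- gower_matrix(real, syn, cols = colsB)
  topk <- function(drow) order(drow)[seq_len(k)]
  succ <- mean(vapply(seq_len(nrow(DA)), function(i)
    length(intersect(topk(DA[i, ]), topk(DB[i, ]))) > 0, TRUE))
  # P(two random k-subsets of m items intersect)
  base <- 1 - exp(lchoose(m - k, k) - lchoose(m, k))
  attack_result(succ, base)
}

#' Multivariate singling-out attack risk
#'
#' Each attack predicate is the conjunction over all attributes of the
#' conditions read off one sampled synthetic record (categorical equality;
#' numeric within `aia_tolerance * range`). A predicate succeeds when it
#' matches exactly one real record. The baseline builds predicates the
#' same way from an independent table drawn from the same schema.
#'
#' @param real,syn `clinical_table`s over the same schema.
#' @param cfg a [privacy_config()].
#' @param baseline_table independent `clinical_table`; defaults to a fresh
#'   fixture draw from the schema with a seed derived from `seed`.
#' @param seed seed for predicate sampling.
#' @return an `attack_result`.
#' @export
singling_out_risk <- function(real, syn, cfg = privacy_config(),
                              baseline_table = NULL, seed = 1) {
  if (is.null(baseline_table))
    baseline_table <- generate_fixture(real$schema, nrow(real$data),
                                       seed = derive_seed(seed, "so-baseline"))
  rate <- function(src) {
    m <- nrow(src$data)
    ix <- with_seed(seed, sample.int(m, cfg$n_attacks, replace = TRUE))
    # match counts of each predicate against the real table
    hits <- matrix(TRUE, nrow(real$data), cfg$n_attacks)
    for (cs in real$schema$columns) {
      rv <- real$data[[cs$name]]
      sv <- src$data[[cs$name]][ix]
      hits <- hits & if (cs$kind == "categorical") {
        outer(rv, sv, "==")
      } else {
        tol <- cfg$aia_tolerance * (cs$range[2] - cs$range[1])
        abs(outer(rv, sv, "-")) <= tol
      }
    }
    mean(colSums(hits) == 1)
  }
  attack_result(rate(syn), rate(baseline_table))
}
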