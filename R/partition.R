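# Client partitioning for the three federated data-distribution scenarios:
# B (balanced), IB (size-imbalanced: N-1 minority nodes each holding 5% of
# rows) and IB_non_iid (age-skewed allocation via per-stratum Dirichlet
# draws). Plans are computed before any training and are serializable, so
# every run is traceable to its partition.

new_partition_plan <- function(scenario, N, assignments, seed,
                               alpha = NULL, minority_frac = NULL) {
  assignments <- lapply(assignments, function(ix) sort(as.integer(ix)))
  n <- sum(lengths(assignments))
  all_ix <- sort(unname(unlist(assignments)))
  if (!identical(all_ix, seq_len(n)))
    stop("assignments must be disjoint and cover all row indices")
  if (any(lengths(assignments) == 0)) stop("every node must be nonempty")
  if (!N %in% c(3, 5, 7, 10) && N != 1)
    warning("node count ", N, " outside the study grid {3, 5, 7, 10}")
  structure(list(scenario = scenario, N = N, assignments = assignments,
                 seed = seed, alpha = alpha, minority_frac = minority_frac),
            class = "partition_plan")
}

#' @export
print.partition_plan <- function(x, ...) {
  cat("partition_plan:", x$scenario, "-", x$N, "nodes, sizes:",
      paste(lengths(x$assignments), collapse = ", "), "\n")
  invisible(x)
}

#' Balanced (B) partition
#'
#' Uniformly random disjoint node sets of size `floor(n/N)`; the `n mod N`
#' leftover rows are spread one per node over the first nodes.
#'
#' @param n number of rows.
#' @param N node count.
#' @param seed integer seed.
#' @return a `partition_plan`.
#' @export
partition_balanced <- function(n, N, seed = 1) {
  if (N > n) stop("cannot split ", n, " rows across ", N, " nodes")
  sizes <- rep(floor(n / N), N)
  rem <- n - sum(sizes)
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  idx <- with_seed(seed, sample.int(n))
  new_partition_plan("B", N, split(idx, rep(seq_len(N), sizes)), seed)
}

#' Imbalanced (IB) partition
#'
#' `N - 1` minority nodes each receive `round(frac * n)` randomly chosen
#' rows; the last node receives everything left.
#'
#' @param n number of rows.
#' @param N node count.
#' @param frac minority fraction (default 0.05).
#' @param seed integer seed.
#' @return a `partition_plan`.
#' @export
partition_imbalanced <- function(n, N, frac = 0.05, seed = 1) {
  m <- round(frac * n)
  if (m < 1 || (N - 1) * m >= n)
    stop("infeasible minority fraction ", frac, " for n = ", n,
         ", N = ", N)
  idx <- with_seed(seed, sample.int(n))
  sizes <- c(rep(m, N - 1), n - (N - 1) * m)
  new_partition_plan("IB", N, split(idx, rep(seq_len(N), sizes)), seed,
                     minority_frac = frac)
}

#' Non-IID (IB_non_iid) partition by Dirichlet allocation over age strata
#'
#' Rows are binned into `n_bins` quantile strata of the conditioning column;
#' within each stratum, per-node allocation proportions are drawn from a
#' symmetric Dirichlet(`alpha`) and rows are dealt out without replacement
#' accordingly. Large `alpha` approaches the balanced scenario; small
#' `alpha` concentrates each stratum on few nodes. An empty node is repaired
#' by moving one row from the largest node.
#'
#' @param table a [clinical_table()].
#' @param cond_col continuous conditioning column (default the schema's
#'   flagged column, `age`).
#' @param N node count.
#' @param alpha Dirichlet concentration (study value 10).
#' @param n_bins number of quantile strata (default `N`).
#' @param seed integer seed.
#' @return a `partition_plan`.
#' @export
partition_dirichlet_noniid <- function(table, cond_col = NULL, N,
                                       alpha = 10, n_bins = N, seed = 1) {
  schema <- table$schema
  if (is.null(cond_col)) {
    flag <- vapply(schema$columns, function(cs) cs$conditioning, TRUE)
    cond_col <- schema_names(schema)[flag]
  }
  cs <- schema_col(schema, cond_col)
  if (cs$kind != "continuous") stop("conditioning column must be continuous")
  stopifnot(alpha > 0, n_bins >= 2)
  v <- table$data[[cond_col]]
  n <- length(v)
  br <- unique(stats::quantile(v, probs = seq(0, 1, length.out = n_bins + 1)))
  if (length(br) - 1 < n_bins) {
    warning("reducing strata from ", n_bins, " to ", length(br) - 1,
            " (too few distinct values)")
  }
  strata <- cut(v, breaks = br, include.lowest = TRUE, labels = FALSE)
  assignments <- with_seed(seed, {
    buckets <- rep(list(integer(0)), N)
    for (s in sort(unique(strata))) {
      rows <- which(strata == s)
      rows <- rows[sample.int(length(rows))]
      g <- stats::rgamma(N, shape = alpha)
      pr <- g / sum(g)
      counts <- floor(pr * length(rows))
      short <- length(rows) - sum(counts)
      if (short > 0) {
        extra <- order(pr * length(rows) - counts, decreasing = TRUE)[seq_len(short)]
        counts[extra] <- counts[extra] + 1L
      }
      node_of <- rep(seq_len(N), counts)
      for (i in seq_len(N))
        buckets[[i]] <- c(buckets[[i]], rows[node_of == i])
    }
    for (i in seq_len(N)) {
      if (length(buckets[[i]]) == 0) {
        donor <- which.max(lengths(buckets))
        buckets[[i]] <- buckets[[donor]][1]
        buckets[[donor]] <- buckets[[donor]][-1]
      }
    }
    buckets
  })
  new_partition_plan("IB_non_iid", N, assignments, seed, alpha = alpha)
}

#' Build the partition plan for a named scenario
#'
#' @param scenario `"B"`, `"IB"` or `"IB_non_iid"`.
#' @param table the `clinical_table` being partitioned.
#' @param N node count.
#' @param seed integer seed.
#' @param ... passed to the scenario's partition function.
#' @return a `partition_plan`.
#' @export
make_partition <- function(scenario, table, N, seed = 1, ...) {
  switch(match.arg(scenario, c("B", "IB", "IB_non_iid")),
         B = partition_balanced(nrow(table$data), N, seed),
         IB = partition_imbalanced(nrow(table$data), N, seed = seed, ...),
         IB_non_iid = partition_dirichlet_noniid(table, N = N, seed = seed, ...))
}

#' Serialize a partition plan to JSON
#' @param plan a `partition_plan`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_partition_plan <- function(plan, path) {
  jsonlite::write_json(unclass(plan), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a partition plan written by [write_partition_plan()]
#' @param path file path.
#' @return a `partition_plan`.
#' @export
read_partition_plan <- function(path) {
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_partition_plan(js$scenario, js$N, js$assignments, js$seed,
                     alpha = js$alpha, minority_frac = js$minority_frac)
}
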