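# Horizontal federated training simulation. Every round the server
# broadcasts the global weights, each client runs its local epochs on its
# own partition and the server aggregates by sample-count-weighted averaging
# (FedAvg). All clients participate every round. Client environments persist
# across rounds: the broadcast overwrites weights only, while optimizer
# moments and the client's RNG stream continue locally — which makes
# single-node federation bitwise identical to centralized training.

#' Federated training configuration
#'
#' @param N node count (must match the partition plan).
#' @param rounds federation rounds (study value 500).
#' @param local_epochs local passes per round; the default 1 makes the total
#'   local budget equal a centralized run of `rounds` epochs.
#' @param aggregation only `"fedavg"` is implemented.
#' @param seed integer seed for model initialisation (all clients share the
#'   same initial weights and RNG stream).
#' @return a `fed_config` list.
#' @export
fed_config <- function(N, rounds = 500, local_epochs = 1,
                       aggregation = "fedavg", seed = 1) {
  stopifnot(rounds >= 0, local_epochs >= 1)
  aggregation <- match.arg(aggregation, "fedavg")
  structure(list(N = N, rounds = rounds, local_epochs = local_epochs,
                 aggregation = aggregation, seed = seed),
            class = "fed_config")
}

#' Sample-count-weighted federated average of weight vectors
#'
#' @param weight_sets list of equal-length numeric weight vectors.
#' @param counts per-client sample counts (all > 0).
#' @return elementwise `sum(n_i w_i) / sum(n_i)`.
#' @export
fedavg <- function(weight_sets, counts) {
  stopifnot(length(weight_sets) == length(counts), all(counts > 0))
  len <- unique(vapply(weight_sets, length, 0L))
  if (length(len) != 1) stop("weight vectors have mismatched lengths")
  out <- numeric(len)
  tot <- sum(counts)
  for (i in seq_along(weight_sets)) out <- out + weight_sets[[i]] * (counts[i] / tot)
  out
}

#' Run a federated training simulation
#'
#' @param kind model kind (`"ctgan"` or `"diffusion"`).
#' @param table the full `clinical_table` (clients see only their partition).
#' @param plan a `partition_plan` with `N` matching `fed$N`.
#' @param tr the transformer fitted on the FULL table (shared by all
#'   clients).
#' @param fed a [fed_config()].
#' @param config optional model configuration.
#' @return the final global `generator_state` (with `rounds = 0`, the
#'   initialisation weights).
#' @export
run_federation <- function(kind, table, plan, tr, fed, config = NULL) {
  if (plan$N != fed$N) stop("plan N (", plan$N, ") != fed N (", fed$N, ")")
  if (any(lengths(plan$assignments) == 0)) stop("empty client partition")
  global <- generator_state(kind, tr, config, seed = fed$seed)
  if (fed$rounds == 0) return(global)
  clients <- lapply(seq_len(fed$N), function(i) copy_state(global))
  tables <- lapply(plan$assignments, function(ix) ct_subset(table, ix))
  counts <- lengths(plan$assignments)
  w_global <- get_weights(global)
  for (r in seq_len(fed$rounds)) {
    ws <- vector("list", fed$N)
    for (i in seq_len(fed$N)) {
      set_weights(clients[[i]], w_global)
      train_model(clients[[i]], tables[[i]], epochs = fed$local_epochs)
      ws[[i]] <- get_weights(clients[[i]])
    }
    w_global <- fedavg(ws, counts)
  }
  set_weights(global, w_global)
  # carry sampler state (e.g. the CTGAN conditional sampler) from a client:
  # all clients share the globally fitted transformer, but level frequencies
  # are taken from the full table for generation.
  if (kind == "ctgan") {
    global$cond_samplers <- build_cond_sampler(global$cond, table)
  }
  if (kind == "resampler") global$train_rows <- table
  global$epochs_done <- clients[[1]]$epochs_done
  global
}
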