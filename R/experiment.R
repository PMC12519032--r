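# Experiment orchestration: the grid of {model kind} x {baseline, B, IB,
# IB_non_iid} x {node count}, the 10-fold generation/evaluation protocol
# (one trained model per cell, `folds` independently sampled synthetic
# tables) and the fold-wise pooled t-test comparison protocol.

#' Experiment grid configuration
#'
#' @param models model kinds to run.
#' @param scenarios federated scenarios (besides the centralized baseline).
#' @param nodes node counts (study grid 3, 5, 7, 10).
#' @param folds synthetic datasets generated and scored per cell.
#' @param epochs centralized training epochs / total local passes.
#' @param rounds federation rounds (with `local_epochs = 1`, the federated
#'   budget matches `epochs`).
#' @param local_epochs local passes per round.
#' @param base_seed seed from which every cell/fold seed is derived.
#' @param significance significance level for the comparisons.
#' @param metrics metric subset to compute per fold.
#' @param model_configs optional named list of model configurations
#'   (defaults per kind, with `epochs`/`rounds` applied).
#' @return an `experiment_config` list.
#' @export
experiment_config <- function(models = c("ctgan", "diffusion"),
                              scenarios = c("B", "IB", "IB_non_iid"),
                              nodes = c(3, 5, 7, 10),
                              folds = 10,
                              epochs = 100, rounds = 100, local_epochs = 1,
                              base_seed = 1,
                              significance = 0.05,
                              metrics = c("cs_phik", "dla_auc", "dla_f1",
                                          "dla_recall", "vendi",
                                          "hellinger_mean", "ddplot_r2",
                                          "mia", "aia", "linkability",
                                          "singling_out"),
                              model_configs = NULL) {
  stopifnot(folds >= 2, significance > 0, significance < 1)
  structure(list(models = models, scenarios = scenarios, nodes = nodes,
                 folds = folds, epochs = epochs, rounds = rounds,
                 local_epochs = local_epochs, base_seed = base_seed,
                 significance = significance, metrics = metrics,
                 model_configs = model_configs),
            class = "experiment_config")
}

cell_model_config <- function(cfg, kind) {
  mc <- cfg$model_configs[[kind]]
  if (!is.null(mc)) return(mc)
  switch(kind,
         ctgan = ctgan_config(epochs = cfg$epochs),
         diffusion = diffusion_config(epochs = cfg$epochs, n_steps = 100),
         resampler = list(epochs = 1))
}

#' Score one synthetic fold against the real table
#'
#' @param real the real `clinical_table` (the full fixture).
#' @param syn one generated `clinical_table`.
#' @param metrics metric names to compute.
#' @param fold_seed seed for the fold's stochastic metrics (DLA split,
#'   attack baselines, the MIA control draw).
#' @param phik_real optional cached [phik_matrix()] of `real`.
#' @return named list of metric values.
#' @export
evaluate_fold <- function(real, syn,
                          metrics = c("cs_phik", "dla_auc"),
                          fold_seed = 1, phik_real = NULL) {
  out <- list()
  if ("cs_phik" %in% metrics) {
    if (is.null(phik_real)) phik_real <- phik_matrix(real)
    out$cs_phik <- matrix_cosine_similarity(phik_real, phik_matrix(syn))
  }
  if (any(c("dla_auc", "dla_f1", "dla_recall") %in% metrics)) {
    r <- dla(real, syn, seed = fold_seed)
    out$dla_auc <- r$auc; out$dla_f1 <- r$f1; out$dla_recall <- r$recall
  }
  if ("vendi" %in% metrics) out$vendi <- vendi_score(syn)
  if ("hellinger_mean" %in% metrics) out$hellinger_mean <- mean_hellinger(real, syn)
  if ("ddplot_r2" %in% metrics) out$ddplot_r2 <- ddplot_r2(real, syn)
  pcfg <- privacy_config()
  if ("mia" %in% metrics) {
    control <- generate_fixture(real$schema, nrow(real$data),
                                seed = derive_seed(fold_seed, "mia-control"))
    out$mia <- mia_risk(real, control, syn, pcfg)$risk
  }
  if ("aia" %in% metrics) out$aia <- aia_risk(real, syn, pcfg, seed = fold_seed)$risk
  if ("linkability" %in% metrics)
    out$linkability <- linkability_risk(real, syn, cfg = pcfg)$risk
  if ("singling_out" %in% metrics)
    out$singling_out <- singling_out_risk(real, syn, pcfg, seed = fold_seed)$risk
  out[intersect(metrics, names(out))]
}

train_cell <- function(cfg, kind, scenario, N, fixture, tr, cell_seed) {
  mc <- cell_model_config(cfg, kind)
  if (scenario == "baseline") {
    st <- generator_state(kind, tr, mc, seed = cell_seed)
    train_model(st, fixture, epochs = cfg$epochs)
  } else {
    plan <- make_partition(scenario, fixture, N,
                           seed = derive_seed(cell_seed, "partition"))
    fed <- fed_config(N, rounds = cfg$rounds,
                      local_epochs = cfg$local_epochs, seed = cell_seed)
    run_federation(kind, fixture, plan, tr, fed, mc)
  }
}

#' Run the experiment grid
#'
#' Per cell: the transformer is fitted once on the full fixture, the model
#' is trained once (centralized for the baseline, federated otherwise),
#' then `folds` synthetic tables of fixture size are generated with
#' distinct derived fold seeds and each is scored with the requested
#' metrics. A failing cell is logged and skipped, not fatal to the grid.
#'
#' @param cfg an [experiment_config()].
#' @param fixture the real `clinical_table`.
#' @param tr optional pre-fitted transformer (fitted on `fixture` if
#'   missing).
#' @return a `metric_table` data.frame with one row per (model, scenario,
#'   N, fold).
#' @export
run_experiment <- function(cfg, fixture, tr = NULL) {
  tr <- tr %||% fit_transformer(fixture)
  cells <- list()
  for (m in cfg$models) cells[[length(cells) + 1]] <- list(model = m, scenario = "baseline", N = 1L)
  for (m in cfg$models)
    for (sc in cfg$scenarios)
      for (N in cfg$nodes)
        cells[[length(cells) + 1]] <- list(model = m, scenario = sc, N = as.integer(N))
  phik_real <- if ("cs_phik" %in% cfg$metrics) phik_matrix(fixture)
  rows <- list()
  for (cell in cells) {
    cell_seed <- derive_seed(cfg$base_seed, cell$model, cell$scenario, cell$N)
    st <- tryCatch(
      train_cell(cfg, cell$model, cell$scenario, cell$N, fixture, tr, cell_seed),
      error = function(e) {
        warning("cell ", cell$model, "/", cell$scenario, "/", cell$N,
                " failed: ", conditionMessage(e))
        NULL
      })
    if (is.null(st)) next
    for (f in seq_len(cfg$folds)) {
      fold_seed <- derive_seed(cell_seed, "fold", f)
      syn <- sample_synthetic(st, nrow(fixture$data), seed = fold_seed)
      vals <- evaluate_fold(fixture, syn, cfg$metrics, fold_seed, phik_real)
      rows[[length(rows) + 1]] <- cbind(
        data.frame(model = cell$model, scenario = cell$scenario,
                   N = cell$N, fold = f),
        as.data.frame(vals))
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("metric_table", "data.frame")
  attr(out, "config") <- cfg
  out
}

#' Per-cell mean and standard deviation summary
#'
#' @param mt a `metric_table` from [run_experiment()].
#' @return data.frame with one row per (model, scenario, N, metric) and
#'   columns `mu`, `sigma`.
#' @export
summarize_metrics <- function(mt) {
  metrics <- setdiff(names(mt), c("model", "scenario", "N", "fold"))
  cells <- unique(mt[c("model", "scenario", "N")])
  rows <- list()
  for (i in seq_len(nrow(cells))) {
    sel <- mt$model == cells$model[i] & mt$scenario == cells$scenario[i] &
      mt$N == cells$N[i]
    for (met in metrics) {
      v <- mt[[met]][sel]
      rows[[length(rows) + 1]] <- data.frame(
        model = cells$model[i], scenario = cells$scenario[i],
        N = cells$N[i], metric = met,
        mu = mean(v), sigma = stats::sd(v))
    }
  }
  do.call(rbind, rows)
}

#' Pooled-variance two-sample t test on fold values
#'
#' Student's t with pooled variance; `df = n_a + n_b - 2` (18 at the
#' study's 10 folds per group). When both groups have zero variance the
#' test is skipped with a flag, mirroring the dashes in the study's result
#' tables.
#'
#' @param a,b numeric fold-value vectors.
#' @return a `t_test_result` with `t`, `df`, `p`, `skipped`.
#' @export
two_sample_t_test <- function(a, b) {
  na <- length(a); nb <- length(b)
  stopifnot(na >= 2, nb >= 2)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  if (sp2 <= 0) {
    return(structure(list(t = NA_real_, df = na + nb - 2, p = NA_real_,
                          skipped = TRUE, reason = "standard deviation is zero"),
                     class = "t_test_result"))
  }
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2
  structure(list(t = t, df = df, p = 2 * stats::pt(-abs(t), df),
                 skipped = FALSE, reason = NULL),
            class = "t_test_result")
}

#' Statistical comparison report over a metric table
#'
#' Emits (i) baseline-vs-each-federated-cell tests per metric and model
#' and (ii) adjacent node-count pair tests (3 vs 5, 5 vs 7, 7 vs 10)
#' within each scenario, flagging significance at the configured level.
#'
#' @param mt a `metric_table`.
#' @param significance significance level (default from the config, else
#'   0.05).
#' @param adjust `"none"` (the study's protocol) or `"BH"` for a
#'   Benjamini-Hochberg correction across the report.
#' @return data.frame of comparisons with `t`, `df`, `p`, `significant`,
#'   `skipped`.
#' @export
compare_cells <- function(mt, significance = NULL, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  cfg <- attr(mt, "config")
  significance <- significance %||% (cfg$significance %||% 0.05)
  metrics <- setdiff(names(mt), c("model", "scenario", "N", "fold"))
  fold_vals <- function(m, sc, N, met)
    mt[[met]][mt$model == m & mt$scenario == sc & mt$N == N]
  rows <- list()
  add_row <- function(model, metric, comparison, a, b) {
    if (length(a) == 0 || length(b) == 0) {
      rows[[length(rows) + 1]] <<- data.frame(
        model = model, metric = metric, comparison = comparison,
        t = NA, df = NA, p = NA, significant = NA, skipped = TRUE,
        reason = "cell unavailable")
      return(invisible())
    }
    tt <- two_sample_t_test(a, b)
    rows[[length(rows) + 1]] <<- data.frame(
      model = model, metric = metric, comparison = comparison,
      t = tt$t, df = tt$df, p = tt$p,
      significant = if (tt$skipped) NA else tt$p < significance,
      skipped = tt$skipped,
      reason = tt$reason %||% "")
  }
  for (m in unique(mt$model)) {
    fed <- unique(mt[mt$model == m & mt$scenario != "baseline",
                     c("scenario", "N")])
    for (met in metrics) {
      base_v <- fold_vals(m, "baseline", 1L, met)
      for (i in seq_len(nrow(fed))) {
        add_row(m, met,
                paste0("baseline_vs_", fed$scenario[i], "_", fed$N[i], "N"),
                base_v, fold_vals(m, fed$scenario[i], fed$N[i], met))
      }
      for (sc in unique(fed$scenario)) {
        Ns <- sort(unique(fed$N[fed$scenario == sc]))
        if (length(Ns) < 2) next
        for (i in seq_len(length(Ns) - 1)) {
          add_row(m, met,
                  paste0(sc, "_", Ns[i], "N_vs_", Ns[i + 1], "N"),
                  fold_vals(m, sc, Ns[i], met),
                  fold_vals(m, sc, Ns[i + 1], met))
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  if (adjust == "BH") {
    ok <- !out$skipped
    out$p[ok] <- stats::p.adjust(out$p[ok], method = "BH")
    out$significant[ok] <- out$p[ok] < significance
  }
  out
}
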