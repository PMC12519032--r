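stub_config <- function(base_seed = 5) {
  experiment_config(models = "resampler", scenarios = "B", nodes = 3,
                    folds = 10, epochs = 1, rounds = 1,
                    metrics = c("cs_phik", "hellinger_mean"),
                    base_seed = base_seed)
}

test_that("each cell yields exactly `folds` evaluated synthetic datasets", {
  ct <- cached("exp_fix", generate_fixture(n = 300, seed = 21))
  tr <- cached("exp_tr", fit_transformer(ct))
  mt <- suppressWarnings(run_experiment(stub_config(), ct, tr))
  counts <- table(mt$scenario)
  expect_equal(unname(counts[["baseline"]]), 10)
  expect_equal(unname(counts[["B"]]), 10)
  expect_equal(mt$fold[mt$scenario == "B"], 1:10)
  s <- summarize_metrics(mt)
  expect_true(all(s$sigma >= 0))
  expect_equal(nrow(s), 2 * 2)   # 2 cells x 2 metrics
})

test_that("fold seeds are a pure function of (base seed, cell, fold)", {
  ct <- cached("exp_fix", generate_fixture(n = 300, seed = 21))
  tr <- cached("exp_tr", fit_transformer(ct))
  mt1 <- suppressWarnings(run_experiment(stub_config(), ct, tr))
  mt2 <- suppressWarnings(run_experiment(stub_config(), ct, tr))
  expect_equal(mt1, mt2)
  mt3 <- suppressWarnings(run_experiment(stub_config(base_seed = 6), ct, tr))
  expect_false(isTRUE(all.equal(mt1$cs_phik, mt3$cs_phik)))
})

test_that("the configured grid enumerates 26 cells", {
  cfg <- experiment_config()
  n_cells <- length(cfg$models) * (1 + length(cfg$scenarios) * length(cfg$nodes))
  expect_equal(n_cells, 26)
})

test_that("pooled t test matches hand computation and the textbook oracle", {
  tt <- two_sample_t_test(c(1, 2, 3, 4), c(2, 3, 4, 5))
  expect_equal(tt$t, -1.095445, tolerance = 1e-6)
  expect_equal(tt$df, 6)
  for (k in 1:20) {
    a <- with_seed_test(500 + k, stats::rnorm(10))
    b <- with_seed_test(600 + k, stats::rnorm(10, mean = 0.3))
    tt <- two_sample_t_test(a, b)
    or <- stats::t.test(a, b, var.equal = TRUE)
    expect_equal(tt$t, unname(or$statistic), tolerance = 1e-9)
    expect_equal(tt$df, unname(or$parameter))
    expect_equal(tt$p, or$p.value, tolerance = 1e-9)
    expect_equal(tt$df, 18)
  }
})

test_that("identical samples give t = 0, p = 1; zero variance skips the test", {
  a <- c(0.1, 0.2, 0.3)
  tt <- two_sample_t_test(a, a)
  expect_equal(tt$t, 0)
  expect_equal(tt$p, 1)
  ttz <- two_sample_t_test(rep(1, 5), rep(1, 5))
  expect_true(ttz$skipped)
  expect_match(ttz$reason, "zero")
})

test_that("the comparison report covers baseline and adjacent-N contrasts", {
  ct <- cached("exp_fix", generate_fixture(n = 300, seed = 21))
  tr <- cached("exp_tr", fit_transformer(ct))
  cfg <- experiment_config(models = "resampler", scenarios = "B",
                           nodes = c(3, 5, 7, 10), folds = 3, epochs = 1,
                           rounds = 1, metrics = "hellinger_mean", base_seed = 5)
  mt <- suppressWarnings(run_experiment(cfg, ct, tr))
  cmp <- compare_cells(mt)
  expect_equal(sum(grepl("^baseline_vs_", cmp$comparison)), 4)
  expect_equal(sum(grepl("N_vs_", cmp$comparison)), 3)  # 3-5, 5-7, 7-10
  expect_true(all(cmp$df[!cmp$skipped] == 4))
  # identical cells are flagged non-significant
  same <- mt
  same$hellinger_mean <- rep(seq(0.1, 0.3, length.out = 3),
                             nrow(mt) / 3)
  cmp2 <- compare_cells(same)
  expect_true(all(!cmp2$significant[grepl("baseline", cmp2$comparison)]))
})

test_that("metrics constant across folds produce sigma 0 and a skipped test", {
  mt <- data.frame(model = "m", scenario = rep(c("baseline", "B"), each = 3),
                   N = rep(c(1L, 3L), each = 3), fold = rep(1:3, 2),
                   metric_x = rep(0.5, 6))
  names(mt)[5] <- "mia"
  class(mt) <- c("metric_table", "data.frame")
  s <- summarize_metrics(mt)
  expect_equal(s$sigma, rep(0, 2))
  cmp <- compare_cells(mt, significance = 0.05)
  expect_true(all(cmp$skipped))
})
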