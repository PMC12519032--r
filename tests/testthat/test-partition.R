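test_that("balanced partitions have near-equal sizes with remainder spread", {
  expect_equal(unname(lengths(partition_balanced(1540, 10, 3)$assignments)),
               rep(154L, 10))
  expect_equal(unname(lengths(partition_balanced(1540, 3, 3)$assignments)),
               c(514L, 513L, 513L))
  expect_equal(unname(lengths(partition_balanced(5, 5, 1)$assignments)),
               rep(1L, 5))
  expect_error(partition_balanced(3, 5, 1), "nodes")
})

test_that("imbalanced partitions give N-1 minority nodes of round(frac n)", {
  expect_equal(unname(lengths(partition_imbalanced(1540, 5, 0.05, 3)$assignments)),
               c(77L, 77L, 77L, 77L, 1232L))
  expect_equal(unname(lengths(partition_imbalanced(1540, 10, 0.05, 3)$assignments)),
               c(rep(77L, 9), 847L))
  expect_error(partition_imbalanced(100, 3, 0.5, 1), "infeasible")
})

test_that("Dirichlet allocation approaches the balanced composition as alpha grows", {
  ct <- fixture_1540()
  plan <- partition_dirichlet_noniid(ct, N = 5, alpha = 1e6, n_bins = 4, seed = 3)
  q <- cut(ct$data$age, stats::quantile(ct$data$age, 0:4 / 4),
           include.lowest = TRUE, labels = FALSE)
  glob <- table(q) / nrow(ct$data)
  for (ix in plan$assignments) {
    comp <- table(factor(q[ix], 1:4)) / length(ix)
    expect_lt(max(abs(comp - glob)), 0.02)
  }
})

test_that("sparse Dirichlet produces strong per-stratum skew", {
  ct <- fixture_1540()
  plan <- partition_dirichlet_noniid(ct, N = 10, alpha = 0.1, seed = 3)
  q <- cut(ct$data$age, stats::quantile(ct$data$age, 0:10 / 10),
           include.lowest = TRUE, labels = FALSE)
  shares <- vapply(plan$assignments, function(ix) sum(q[ix] == 1, na.rm = TRUE), 0)
  m <- mean(shares)
  expect_gt(max(shares), 2 * m)
  expect_lt(min(shares), 0.5 * m)
})

test_that("every scenario conserves and partitions the row set", {
  ct <- fixture_200()
  n <- nrow(ct$data)
  for (plan in list(partition_balanced(n, 5, 11),
                    partition_imbalanced(n, 3, 0.05, 11),
                    partition_dirichlet_noniid(ct, N = 5, seed = 11))) {
    ix <- sort(unname(unlist(plan$assignments)))
    expect_identical(ix, seq_len(n))
    expect_true(all(lengths(plan$assignments) > 0))
  }
})

test_that("partitions are seed-deterministic and seed-sensitive", {
  a <- partition_balanced(500, 5, 7)
  expect_identical(a$assignments, partition_balanced(500, 5, 7)$assignments)
  expect_false(identical(a$assignments, partition_balanced(500, 5, 8)$assignments))
  ct <- fixture_200()
  d1 <- partition_dirichlet_noniid(ct, N = 3, seed = 5)
  expect_identical(d1$assignments,
                   partition_dirichlet_noniid(ct, N = 3, seed = 5)$assignments)
})

test_that("partition plans serialize to JSON and back", {
  plan <- partition_imbalanced(500, 5, 0.05, 13)
  path <- tempfile(fileext = ".json")
  write_partition_plan(plan, path)
  rt <- read_partition_plan(path)
  expect_identical(rt$assignments, plan$assignments)
  expect_equal(rt$scenario, plan$scenario)
  expect_equal(rt$minority_frac, plan$minority_frac)
})

test_that("node counts off the study grid warn but work", {
  expect_warning(partition_balanced(100, 4, 1), "grid")
})
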