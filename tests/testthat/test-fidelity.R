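test_that("phi-k matches its closed relationships", {
  x <- with_seed_test(1, stats::rnorm(10000))
  z <- with_seed_test(2, stats::rnorm(10000))
  qb <- function(v) cut(v, stats::quantile(v, 0:10 / 10), include.lowest = TRUE)
  # perfect dependence
  expect_gte(fedtabsim:::phik_from_contingency(table(qb(x), qb(x))), 0.99)
  # independence (continuous and binary)
  expect_lt(fedtabsim:::phik_from_contingency(table(qb(x), qb(z))), 0.05)
  b1 <- with_seed_test(3, stats::rbinom(10000, 1, 0.5))
  b2 <- with_seed_test(4, stats::rbinom(10000, 1, 0.5))
  expect_lt(fedtabsim:::phik_from_contingency(table(b1, b2)), 0.05)
  # recovers the latent correlation of a binned bivariate normal
  y <- 0.6 * x + sqrt(1 - 0.36) * z
  expect_equal(fedtabsim:::phik_from_contingency(table(qb(x), qb(y))), 0.6,
               tolerance = 0.05)
})

test_that("the phi-k matrix is symmetric with unit diagonal in [0, 1]", {
  M <- cached("phik200", phik_matrix(fixture_200()))
  expect_true(isSymmetric(M))
  expect_equal(unname(diag(M)), rep(1, 12))
  expect_gte(min(M), 0)
  expect_lte(max(M), 1)
  # coupled pair clearly above an uncoupled one at fixture scale
  M2 <- cached("phik1540", phik_matrix(fixture_1540()))
  expect_gt(M2["wbc", "bm_blast_pct"], M2["age", "platelets"] + 0.2)
})

test_that("a constant column correlates zero with everything", {
  ct <- fixture_200()
  ct$data$wbc <- rep(10, 200)
  M <- phik_matrix(ct)
  expect_equal(unname(M["wbc", -2]), rep(0, 11))
})

test_that("matrix cosine similarity follows the hand cases and an oracle", {
  A <- diag(12)
  expect_equal(matrix_cosine_similarity(A, A), 1)
  x <- matrix(0, 3, 3); x[1, 2] <- 1
  y <- matrix(0, 3, 3); y[1, 3] <- 1
  expect_equal(matrix_cosine_similarity(x, y), 0)
  a <- matrix(0, 3, 3); a[1, 2] <- 1; a[1, 3] <- 1
  b <- matrix(0, 3, 3); b[1, 2] <- 1
  expect_equal(matrix_cosine_similarity(a, b), 1 / sqrt(2), tolerance = 1e-9)
  # brute-force oracle on random symmetric matrices
  for (k in 1:5) {
    M1 <- with_seed_test(100 + k, {m <- matrix(stats::runif(144), 12); (m + t(m)) / 2})
    M2 <- with_seed_test(200 + k, {m <- matrix(stats::runif(144), 12); (m + t(m)) / 2})
    v1 <- M1[upper.tri(M1)]; v2 <- M2[upper.tri(M2)]
    oracle <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
    expect_equal(matrix_cosine_similarity(M1, M2), oracle, tolerance = 1e-12)
  }
})

test_that("Vendi score hits its closed-form kernels and bounds", {
  sch <- fixture_200()$schema
  one <- clinical_table(sch, fixture_200()$data[rep(7, 10), ])
  expect_equal(vendi_score(one), 1, tolerance = 1e-9)
  # kernel-level closed forms: rank-1, orthogonal (K = I), two orthogonal rows
  expect_equal(fedtabsim:::vendi_kernel_score(matrix(1, 10, 3)), 1,
               tolerance = 1e-9)
  expect_equal(fedtabsim:::vendi_kernel_score(diag(4)), 4, tolerance = 1e-9)
  expect_equal(fedtabsim:::vendi_kernel_score(rbind(c(1, 0), c(0, 2))), 2,
               tolerance = 1e-9)
  # bounds on random tables
  for (k in 1:3) {
    tab <- generate_fixture(n = 50, seed = 300 + k)
    v <- vendi_score(tab)
    expect_gte(v, 1)
    expect_lte(v, 50)
  }
})

test_that("Hellinger distance: identity, disjoint supports, Bernoulli closed form", {
  expect_equal(hellinger_distance(c(1, 2, 1, 2), c(1, 2, 1, 2), "categorical"), 0)
  expect_equal(hellinger_distance(c(1, 1), c(2, 2), "categorical"), 1)
  expect_equal(hellinger_distance(c(0, 1, 0, 1), c(1, 1, 1, 1), "categorical"),
               sqrt(1 - sqrt(0.5)), tolerance = 1e-12)
  x <- with_seed_test(5, stats::runif(2000))
  expect_equal(hellinger_distance(x, x, "continuous"), 0)
  ct <- fixture_200()
  expect_equal(mean_hellinger(ct, ct), 0)
})

test_that("depth-depth R2: identity, gross mismatch, permutation invariance", {
  ct <- fixture_1540()
  expect_equal(ddplot_r2(ct, ct), 1, tolerance = 1e-9)
  half1 <- ct_subset(ct, 1:770)
  half2 <- ct_subset(ct, 771:1540)
  shifted <- half2
  for (nm in continuous_cols(ct$schema)) {
    cs <- ct$schema$columns[[match(nm, names(ct$data))]]
    shifted$data[[nm]] <- pmin(cs$range[2],
                               shifted$data[[nm]] + 10 * stats::sd(ct$data[[nm]]))
  }
  expect_lt(suppressWarnings(ddplot_r2(half1, shifted)), 0.2)
  perm <- ct_subset(half2, with_seed_test(1, sample.int(770)))
  expect_equal(ddplot_r2(half1, perm), ddplot_r2(half1, half2), tolerance = 1e-9)
})

test_that("detection analysis is null-calibrated and separates gross shifts", {
  ct <- cached("dla_fix", generate_fixture(n = 1200, seed = 17))
  half1 <- ct_subset(ct, 1:600)
  half2 <- ct_subset(ct, 601:1200)
  r0 <- dla(half1, half2, seed = 1)
  expect_gte(r0$auc, 0.45)
  expect_lte(r0$auc, 0.60)
  shifted <- half2
  shifted$data$hb <- pmin(16, shifted$data$hb + 20 * stats::sd(ct$data$hb))
  r1 <- dla(half1, shifted, seed = 1)
  expect_gte(r1$auc, 0.99)
  expect_equal(nrow(r0$per_classifier), 6)
  expect_true(all(r0$per_classifier$auc >= 0 & r0$per_classifier$auc <= 1))
  expect_equal(r0$f1, max(r0$per_classifier$f1))
})

test_that("DLA recall is the synthetic-class true-positive rate", {
  ct <- cached("dla_fix", generate_fixture(n = 1200, seed = 17))
  r <- dla(ct_subset(ct, 1:600), ct_subset(ct, 601:1200), seed = 3,
           roster = "logistic")
  expect_gte(r$recall, 0)
  expect_lte(r$recall, 1)
  expect_equal(r$best, "logistic")
})
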