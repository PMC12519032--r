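privacy_views <- function(schema) {
  nms <- vapply(schema$columns, `[[`, "", "name")
  # interleave kinds so both views carry continuous columns (records stay
  # distinctive in each view)
  list(A = nms[c(1, 2, 3, 6, 8, 10)], B = nms[c(4, 5, 7, 9, 11, 12)])
}

test_that("Gower distance matches hand cases and is a metric", {
  sch <- fixture_200()$schema
  a <- fixture_200()$data[1, ]
  expect_equal(gower_distance(a, a, sch), 0)
  # one numeric column, range 10: |2 - 7| / 10 = 0.5
  nsch <- table_schema(list(
    column_spec("v", "continuous", "tnorm", c(mean = 5, sd = 2),
                range = c(0, 10), conditioning = TRUE)), 2, diag(1))
  expect_equal(gower_distance(list(v = 2), list(v = 7), nsch), 0.5)
  # all-categorical full mismatch
  csch <- table_schema(list(
    column_spec("x", "continuous", "tnorm", c(mean = 0, sd = 1),
                range = c(0, 1), conditioning = TRUE),
    column_spec("s", "categorical", levels = c("a", "b"), probs = c(.5, .5)),
    column_spec("t", "categorical", levels = c("a", "b"), probs = c(.5, .5))), 2, diag(3))
  expect_equal(gower_distance(list(x = 0, s = 1, t = 1),
                              list(x = 1, s = 2, t = 2), csch), 1)
  # metric properties on random triples
  ct <- fixture_200()
  for (k in 1:20) {
    ix <- with_seed_test(400 + k, sample.int(200, 3))
    r <- lapply(ix, function(i) ct$data[i, ])
    dab <- gower_distance(r[[1]], r[[2]], sch)
    dba <- gower_distance(r[[2]], r[[1]], sch)
    dac <- gower_distance(r[[1]], r[[3]], sch)
    dcb <- gower_distance(r[[3]], r[[2]], sch)
    expect_equal(dab, dba)
    expect_gte(dab, 0)
    expect_lte(dab, 1)
    expect_lte(dab, dac + dcb + 1e-12)
  }
})

test_that("membership inference saturates on copied data and nulls out otherwise", {
  trn <- cached("priv_train", generate_fixture(n = 600, seed = 41))
  ctl <- cached("priv_ctl", generate_fixture(n = 600, seed = 42))
  ind <- cached("priv_ind", generate_fixture(n = 600, seed = 43))
  expect_equal(mia_risk(trn, ctl, trn)$risk, 1)
  expect_equal(mia_risk(trn, trn, ind)$risk, 0)
  expect_lte(mia_risk(trn, ctl, ind)$risk, 0.05)
})

test_that("attribute inference saturates on copied data and nulls out otherwise", {
  trn <- cached("priv_train", generate_fixture(n = 600, seed = 41))
  ind <- cached("priv_ind", generate_fixture(n = 600, seed = 43))
  sat <- aia_risk(trn, trn, seed = 1)
  expect_equal(sat$success_rate, 1)
  nul <- aia_risk(trn, ind, seed = 1)
  expect_lte(nul$risk, 0.05)
  expect_equal(nrow(sat$per_column), 12)
  # numeric tolerance: |50 - 50.4| within 0.05 * range 10
  cfg <- privacy_config()
  expect_true(abs(50 - 50.4) <= cfg$aia_tolerance * 10)
})

test_that("linkability saturates on copies (distinct views) and nulls out otherwise", {
  trn <- cached("priv_train", generate_fixture(n = 600, seed = 41))
  ind <- cached("priv_ind", generate_fixture(n = 600, seed = 43))
  v <- privacy_views(trn$schema)
  sat <- linkability_risk(trn, trn, colsA = v$A, colsB = v$B)
  expect_equal(sat$success_rate, 1)
  expect_gte(sat$risk, 0.99)
  expect_lte(linkability_risk(trn, ind, colsA = v$A, colsB = v$B)$risk, 0.05)
  expect_error(linkability_risk(trn, ind, colsA = v$A,
                                colsB = c(v$B[-1], v$A[1])), "disjoint")
})

test_that("singling out isolates unique records and fails on duplicated tables", {
  trn <- cached("priv_train", generate_fixture(n = 600, seed = 41))
  # fully duplicated real table: no predicate can isolate one row
  dup <- clinical_table(trn$schema, trn$data[rep(1:300, 2), ])
  r0 <- singling_out_risk(dup, ct_subset(dup, 1:300), seed = 5)
  expect_equal(r0$success_rate, 0)
  # synthetic = copy of distinct reals, tolerance -> 0 pins its source row
  cfg <- privacy_config(aia_tolerance = 1e-9)
  r1 <- singling_out_risk(trn, trn, cfg, seed = 5)
  expect_equal(r1$success_rate, 1)
  expect_gte(r1$risk, 0)
  expect_lte(r1$risk, 1)
})

test_that("attack risks are zero when attack equals baseline", {
  trn <- cached("priv_train", generate_fixture(n = 600, seed = 41))
  res <- fedtabsim:::attack_result(0.3, 0.3)
  expect_equal(res$risk, 0)
  expect_equal(fedtabsim:::attack_result(0.2, 0.5)$risk, 0)
  expect_equal(fedtabsim:::attack_result(1, 0)$risk, 1)
})
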