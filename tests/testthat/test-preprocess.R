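test_that("mixture fitting recovers the right number of modes", {
  x <- with_seed_test(42, stats::rnorm(2000))
  m1 <- fedtabsim:::fit_column_mixture(x, 10)
  expect_length(m1$means, 1)
  expect_lt(abs(m1$means), 3 / sqrt(2000))  # within 3 SE of 0

  y <- with_seed_test(42, c(stats::rnorm(2500, -5), stats::rnorm(2500, 5)))
  m2 <- fedtabsim:::fit_column_mixture(y, 10)
  expect_length(m2$means, 2)
  expect_equal(m2$means, c(-5, 5), tolerance = 0.1)
})

test_that("constant columns degenerate to a floor-scale single mode", {
  m <- fedtabsim:::fit_column_mixture(rep(3.5, 50), 10)
  expect_equal(m$means, 3.5)
  expect_equal(m$sds, 1e-6)
  expect_equal(m$weights, 1)
})

test_that("one-hot maps cover the schema labels and the encoded width adds up", {
  tr <- transformer_200()
  sch <- fixture_200()$schema
  for (nm in categorical_cols(sch)) {
    cs <- sch$columns[[match(nm, vapply(sch$columns, `[[`, "", "name"))]]
    expect_equal(tr$encoders[[nm]]$width, length(cs$levels))
  }
  # width = sum over continuous (K + 1) + sum over categorical levels
  w <- 0
  for (nm in tr$columns) {
    e <- tr$encoders[[nm]]
    w <- w + if (e$type == "gmm") 1L + length(e$means) else e$width
  }
  expect_equal(encoded_width(tr), w)
  binary <- fit_transformer(
    clinical_table(binary_schema(),
                   generate_fixture(binary_schema(), 100, seed = 3)$data))
  expect_equal(binary$encoders$flag$width, 2)
})

test_that("the normalized scalar follows (v - mu) / (4 sd) with clipping", {
  sch <- binary_schema()
  tab <- generate_fixture(sch, 300, seed = 4)
  tr <- fit_transformer(tab)
  e <- tr$encoders$age
  expect_length(e$means, 1)  # truncated-normal column: one surviving mode
  tab$data$age <- rep(e$means, 300)        # exactly at the mode mean
  enc <- transform_table(tab, tr, deterministic_modes = TRUE)
  expect_equal(max(abs(enc$X[, tr$layout$age$offset + 1])), 0)
  v <- min(e$means + 4 * e$sds, 90)
  tab$data$age <- rep(v, 300)              # the clip boundary
  a <- transform_table(tab, tr,
                       deterministic_modes = TRUE)$X[1, tr$layout$age$offset + 1]
  expect_equal(a, min(1, (v - e$means) / (4 * e$sds)), tolerance = 1e-12)
})

test_that("transform / inverse_transform round-trips (up to clipping)", {
  ct <- fixture_200()
  tr <- transformer_200()
  enc <- transform_table(ct, tr, seed = 5)
  rt <- inverse_transform(enc, tr)
  for (nm in categorical_cols(ct$schema))
    expect_identical(rt$data[[nm]], ct$data[[nm]])
  for (nm in continuous_cols(ct$schema)) {
    a <- enc$X[, tr$layout[[nm]]$offset + 1]
    uncl <- abs(a) < 1
    expect_lt(max(abs(rt$data[[nm]][uncl] - ct$data[[nm]][uncl])), 1e-9)
  }
})

test_that("encoding errors are explicit", {
  ct <- fixture_200()
  tr <- transformer_200()
  bad <- ct
  bad$data$sex[1] <- 5L
  expect_error(transform_table(bad, tr), "sex")
  enc <- transform_table(ct, tr, seed = 1)
  expect_error(inverse_transform(enc$X[, -1], tr), "width")
})

test_that("an all-zero block decodes deterministically to the first position", {
  tr <- transformer_200()
  X <- matrix(0, 3, encoded_width(tr))
  dec <- inverse_transform(X, tr)
  for (nm in categorical_cols(dec$schema))
    expect_equal(dec$data[[nm]], rep(1L, 3))
})

test_that("mode selection: seeded sampling reproducible, argmax deterministic", {
  ct <- fixture_200()
  tr <- transformer_200()
  e1 <- transform_table(ct, tr, seed = 9)
  e2 <- transform_table(ct, tr, seed = 9)
  expect_identical(e1$X, e2$X)
  d1 <- transform_table(ct, tr, deterministic_modes = TRUE)
  d2 <- transform_table(ct, tr, deterministic_modes = TRUE)
  expect_identical(d1$X, d2$X)
})

test_that("transformers serialize to JSON and back", {
  tr <- transformer_200()
  path <- tempfile(fileext = ".json")
  write_transformer(tr, path)
  rt <- read_transformer(path, fixture_200()$schema)
  expect_equal(rt$encoders, tr$encoders, tolerance = 1e-12)
  expect_equal(rt$width, tr$width)
  ct <- fixture_200()
  e1 <- transform_table(ct, tr, seed = 3)
  e2 <- transform_table(ct, rt, seed = 3)
  expect_equal(e1$X, e2$X, tolerance = 1e-12)
})
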