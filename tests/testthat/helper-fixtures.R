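# Shared fixtures, built once per test run (all generated in code).
.fixture_cache <- new.env()

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- expr
  .fixture_cache[[key]]
}

fixture_200 <- function() cached("f200", generate_fixture(n = 200, seed = 2))
transformer_200 <- function() cached("t200", fit_transformer(fixture_200()))
fixture_1540 <- function() cached("f1540", generate_fixture(seed = 1))
transformer_1540 <- function() cached("t1540", fit_transformer(fixture_1540()))

# tiny schema: age plus one binary column (for frequency-recovery checks)
binary_schema <- function(p1 = 0.8) {
  table_schema(
    list(column_spec("age", "continuous", "tnorm", c(mean = 50, sd = 10),
                     range = c(18, 90), conditioning = TRUE),
         column_spec("flag", "categorical", levels = c("0", "1"),
                     probs = c(1 - p1, p1))),
    n_default = 500, correlation = diag(2))
}

with_seed_test <- function(seed, expr) fedtabsim:::with_seed(seed, expr)
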