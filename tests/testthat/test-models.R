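# Generative-model contracts at desk scale: determinism, weight-view
# round trips, schedule arithmetic and distribution recovery on tiny
# schemas. Heavier convergence checks live in the acceptance suite.

test_that("training is a warning no-op below one epoch", {
  tr <- transformer_200()
  st <- generator_state("ctgan", tr, ctgan_config(), seed = 1)
  w0 <- get_weights(st)
  expect_warning(train_model(st, fixture_200(), epochs = 0), "skipped")
  expect_identical(get_weights(st), w0)
})

test_that("training and sampling are deterministic under a fixed seed", {
  tr <- transformer_200()
  ct <- fixture_200()
  run <- function() {
    st <- generator_state("ctgan", tr, ctgan_config(), seed = 11)
    train_ctgan(st, ct, 3)
    get_weights(st)
  }
  expect_identical(run(), run())
  st <- generator_state("diffusion", tr, diffusion_config(n_steps = 50), seed = 4)
  train_diffusion(st, ct, 3)
  s1 <- sample_synthetic(st, 60, seed = 9)
  s2 <- sample_synthetic(st, 60, seed = 9)
  expect_identical(s1$data, s2$data)
  expect_false(identical(s1$data, sample_synthetic(st, 60, seed = 10)$data))
})

test_that("untrained states still emit schema-valid tables", {
  tr <- transformer_200()
  for (kind in c("ctgan", "diffusion")) {
    st <- generator_state(kind, tr,
                          if (kind == "diffusion") diffusion_config(n_steps = 20)
                          else ctgan_config(), seed = 2)
    syn <- sample_synthetic(st, 50, seed = 1)
    expect_equal(dim(syn), c(50L, 12L))
    expect_silent(validate_clinical_table(syn))
  }
  expect_error(sample_synthetic(
    generator_state("ctgan", tr, seed = 1), 0), "m >= 1")
})

test_that("the flat weight view round-trips exactly", {
  tr <- transformer_200()
  for (kind in c("ctgan", "diffusion")) {
    st <- generator_state(kind, tr,
                          if (kind == "diffusion") diffusion_config(n_steps = 20)
                          else ctgan_config(), seed = 3)
    w <- get_weights(st)
    v <- w + stats::rnorm(length(w), sd = 1e-3)
    set_weights(st, v)
    expect_identical(get_weights(st), v)
    set_weights(st, w)
    expect_identical(get_weights(st), w)
    expect_error(set_weights(st, w[-1]), "length")
    # set(get(s)) leaves sampling unchanged
    s1 <- sample_synthetic(st, 40, seed = 5)
    set_weights(st, get_weights(st))
    expect_identical(sample_synthetic(st, 40, seed = 5)$data, s1$data)
  }
})

test_that("the linear beta schedule nearly destroys the signal by step T", {
  cfg <- diffusion_config()   # T = 500, beta 1e-4 .. 0.02
  ab <- cumprod(1 - seq(cfg$beta_start, cfg$beta_end, length.out = cfg$n_steps))
  expect_lt(ab[cfg$n_steps], 0.01)
  st <- generator_state("diffusion", transformer_200(), diffusion_config(), seed = 1)
  expect_equal(st$alpha_bar[cfg$n_steps], ab[cfg$n_steps])
})

test_that("the conditional GAN recovers a binary frequency", {
  sch <- binary_schema(0.8)
  tab <- generate_fixture(sch, 500, seed = 6)
  tr <- fit_transformer(tab)
  st <- generator_state("ctgan", tr, ctgan_config(), seed = 21)
  train_ctgan(st, tab, 200)
  syn <- sample_synthetic(st, 5000, seed = 2)
  p1 <- mean(syn$data$flag == 2)
  expect_gte(p1, 0.7)
  expect_lte(p1, 0.9)
})

test_that("the diffusion model recovers both modes of a bimodal column", {
  sch <- table_schema(
    list(column_spec("value", "continuous", "tnorm", c(mean = 0, sd = 6),
                     range = c(-10, 10), conditioning = TRUE)),
    n_default = 600, correlation = diag(1))
  x <- with_seed_test(8, c(stats::rnorm(300, -5), stats::rnorm(300, 5)))
  tab <- clinical_table(sch, data.frame(value = pmin(10, pmax(-10, x))))
  tr <- fit_transformer(tab)
  expect_length(tr$encoders$value$means, 2)
  st <- generator_state("diffusion", tr, diffusion_config(n_steps = 50), seed = 31)
  train_diffusion(st, tab, 300)
  syn <- sample_synthetic(st, 2000, seed = 3)
  lo <- mean(syn$data$value < 0)
  expect_gte(lo, 0.3)
  expect_lte(lo, 0.7)
})

test_that("training strictly improves detectability over an untrained generator", {
  ct <- fixture_1540()
  tr <- transformer_1540()
  untrained <- generator_state("ctgan", tr, ctgan_config(), seed = 5)
  auc0 <- dla(ct, sample_synthetic(untrained, 1540, seed = 1), seed = 2)$auc
  trained <- generator_state("ctgan", tr, ctgan_config(), seed = 5)
  train_ctgan(trained, ct, 100)
  auc1 <- dla(ct, sample_synthetic(trained, 1540, seed = 1), seed = 2)$auc
  expect_lt(auc1, auc0)
})
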