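test_that("model_spec validates depth and learner", {
  expect_error(model_spec("boosted", depth = 3), "depth")
  expect_s3_class(model_spec("l1_linear"), "model_spec")
})

test_that("lasso attains r2 ~ 1 on a noiseless linear phenotype", {
  sim <- quick_sim(n = 600, p = 40, n_linear = 6, n_pairs = 0,
                   w_l = 1, w_ep = 0, w_eps = 0, seed = 6)
  sp <- split_list(sim$dataset)
  m <- fit_model(sp$train, sp$validation, model_spec("l1_linear"),
                 use_covariates = FALSE)
  expect_gte(m$validation_metric, 0.99)
})

test_that("depth-2 trees capture a planted epistatic interaction; depth-1 cannot", {
  set.seed(20)
  n <- 20000
  g <- matrix(sample(0:2, n * 10, TRUE), n, 10)
  y <- 2 * (g[, 2] == 2 & g[, 5] == 0) + stats::rnorm(n, 0, 0.3)
  ds <- tiny_dataset(g, phenotype = y,
                     split = rep(c("train", "validation", "test"),
                                 c(16000, 2000, 2000)))
  sp <- split_list(ds)
  m1 <- fit_model(sp$train, sp$validation, model_spec("boosted", depth = 1))
  m2 <- fit_model(sp$train, sp$validation, model_spec("boosted", depth = 2))
  expect_gte(m2$validation_metric - m1$validation_metric, 0.1)
  # depth-1 is additive; depth-2 fitted on an interaction is not
  expect_lt(verify_additivity(m1, sp$test), 1e-9)
  expect_gt(verify_additivity(m2, sp$test), 1e-6)
})

test_that("depth-1 and depth-2 agree on a purely additive phenotype", {
  sim <- quick_sim(n = 6000, p = 50, n_linear = 10, n_pairs = 0,
                   w_l = 0.8, w_ep = 0, w_eps = 0.2, seed = 7)
  sp <- split_list(sim$dataset)
  m1 <- fit_model(sp$train, sp$validation, model_spec("boosted", depth = 1),
                  use_covariates = FALSE)
  m2 <- fit_model(sp$train, sp$validation, model_spec("boosted", depth = 2),
                  use_covariates = FALSE)
  p1 <- predict(m1, sp$test); p2 <- predict(m2, sp$test)
  r1 <- r_squared(sp$test$phenotype, p1)
  r2 <- r_squared(sp$test$phenotype, p2)
  se <- se_subsampling(sp$test$phenotype, p2, "r2", seed = 1)
  expect_lt(abs(r1 - r2), 2 * max(se, 0.01))
})

test_that("linear models have zero additivity residual", {
  sim <- quick_sim(n = 800, p = 20, n_linear = 5, n_pairs = 0,
                   w_l = 0.8, w_ep = 0, w_eps = 0.2, seed = 8)
  sp <- split_list(sim$dataset)
  m <- fit_model(sp$train, sp$validation, model_spec("l1_linear"),
                 use_covariates = FALSE)
  expect_lt(verify_additivity(m, sp$test), 1e-9)
})

test_that("predictions are deterministic, order-invariant and stateless", {
  sim <- quick_sim(n = 1000, p = 20, n_linear = 5, n_pairs = 0,
                   w_l = 0.8, w_ep = 0, w_eps = 0.2, seed = 9)
  sp <- split_list(sim$dataset)
  m <- fit_model(sp$train, sp$validation, model_spec("boosted", depth = 2),
                 use_covariates = FALSE)
  x <- sp$test$genotypes
  storage.mode(x) <- "double"
  p <- predict(m, x)
  expect_identical(p, predict(m, x))
  # column order irrelevant when columns are named
  perm <- sample(ncol(x))
  expect_equal(predict(m, x[, perm]), p, tolerance = 1e-12)
  # batch equals row-by-row
  rows <- vapply(1:5, function(i) predict(m, x[i, , drop = FALSE]),
                 numeric(1))
  expect_equal(rows, p[1:5], tolerance = 1e-9)
  expect_error(predict(m, x[, -1]), "missing feature")
})

test_that("restricted mode decomposes into SNP + covariate parts", {
  set.seed(21)
  n <- 6000
  g <- matrix(sample(0:2, n * 8, TRUE), n, 8)
  cov <- cbind(age = stats::rnorm(n), bmi = stats::rnorm(n))
  # true SNP x covariate interaction
  y <- g[, 1] + cov[, "age"] + 1.5 * (g[, 3] == 2) * cov[, "bmi"] +
    stats::rnorm(n, 0, 0.3)
  ds <- tiny_dataset(g, phenotype = y, covariates = cov,
                     split = rep(c("train", "validation", "test"),
                                 c(4800, 600, 600)))
  sp <- split_list(ds)
  res <- fit_model(sp$train, sp$validation,
                   model_spec("boosted", depth = 2,
                              interaction_mode = "restricted"))
  free <- fit_model(sp$train, sp$validation, model_spec("boosted", depth = 2))
  expect_lt(verify_group_decomposition(res, sp$test), 1e-9)
  expect_gt(verify_group_decomposition(free, sp$test), 1e-6)
  # the free model exploits the interaction the restricted one cannot
  expect_gt(free$validation_metric, res$validation_metric)
})

test_that("restricted and free modes agree when no gene-covariate interaction exists", {
  sim <- simulate_dataset(simulation_config(
    n_samples = 6000, n_snps = 30, n_linear = 8, n_epistatic_pairs = 0,
    w_l = 0.8, w_ep = 0, w_eps = 0.2, n_covariates = 2,
    covariate_effect = "linear", seed = 10))
  sp <- split_list(sim$dataset)
  res <- fit_model(sp$train, sp$validation,
                   model_spec("boosted", depth = 2,
                              interaction_mode = "restricted"))
  free <- fit_model(sp$train, sp$validation, model_spec("boosted", depth = 2))
  pr <- predict(res, sp$test); pf <- predict(free, sp$test)
  rr <- r_squared(sp$test$phenotype, pr)
  rf <- r_squared(sp$test$phenotype, pf)
  se <- se_subsampling(sp$test$phenotype, pf, "r2", seed = 2)
  expect_lt(abs(rr - rf), 2 * max(se, 0.02))
})

test_that("validation accuracy degrades as noise weight grows", {
  r2s <- vapply(c(0.2, 0.5, 0.8), function(w_eps) {
    meds <- vapply(1:3, function(seed) {
      sim <- quick_sim(n = 2000, p = 40, n_linear = 8, n_pairs = 0,
                       w_l = 1 - w_eps, w_ep = 0, w_eps = w_eps, seed = seed)
      sp <- split_list(sim$dataset)
      fit_model(sp$train, sp$validation, model_spec("l1_linear"),
                use_covariates = FALSE)$validation_metric
    }, numeric(1))
    stats::median(meds)
  }, numeric(1))
  expect_true(all(diff(r2s) < 0))
})

test_that("an infinite L1 penalty predicts the train mean", {
  sim <- quick_sim(n = 800, p = 20, n_linear = 5, n_pairs = 0,
                   w_l = 0.8, w_ep = 0, w_eps = 0.2, seed = 11)
  sp <- split_list(sim$dataset)
  m <- fit_model(sp$train, sp$validation,
                 model_spec("l1_linear", lambda_path = c(1e9, 1e8)),
                 use_covariates = FALSE)
  p <- predict(m, sp$test)
  expect_equal(unique(round(p, 9)), round(mean(sp$train$phenotype), 9))
  expect_lte(r_squared(sp$test$phenotype, p), 1e-9)
})

test_that("binary fits error on a single-class train split", {
  ds <- tiny_dataset(matrix(sample(0:2, 200, TRUE), 100, 2),
                     phenotype = rep(0L, 100), kind = "binary",
                     split = rep(c("train", "validation"), 50))
  sp <- list(train = get_split(ds, "train"),
             validation = get_split(ds, "validation"))
  expect_error(fit_model(sp$train, sp$validation,
                         model_spec("boosted", depth = 1)), "single class")
})
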