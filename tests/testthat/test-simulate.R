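test_that("config validation catches inconsistent weights and counts", {
  expect_error(simulation_config(w_l = 0.5, w_ep = 0.2, w_eps = 0.2),
               "sum to 1")
  expect_error(simulation_config(n_snps = 50, n_linear = 40,
                                 n_epistatic_pairs = 10), "exceed")
  expect_error(simulation_config(w_l = 0.2, w_ep = 0.6, w_eps = 0.2,
                                 n_epistatic_pairs = 0), "requires")
  expect_error(simulation_config(gene_covariate_pairs = 2,
                                 n_covariates = 0, w_l = 0.6, w_ep = 0.2,
                                 w_eps = 0.2), "covariates")
})

test_that("genotype simulation is deterministic and matches its MAFs", {
  cfg <- simulation_config(n_samples = 10000, n_snps = 30, n_linear = 5,
                           n_epistatic_pairs = 0, maf_range = c(0.05, 0.5),
                           seed = 9)
  a <- simulate_genotypes(cfg)
  b <- simulate_genotypes(cfg)
  expect_identical(a$genotypes, b$genotypes)
  p <- attr(a, "maf")
  emp <- colMeans(a$genotypes) / 2
  se <- sqrt(p * (1 - p) / (2 * cfg$n_samples))
  expect_true(all(abs(emp - p) < 3.5 * se))
})

test_that("independent SNPs are empirically uncorrelated; LD blocks are not", {
  ind <- simulate_genotypes(simulation_config(n_samples = 10000, n_snps = 10,
                                              n_linear = 2,
                                              n_epistatic_pairs = 0,
                                              maf_range = c(0.1, 0.5),
                                              seed = 2))
  expect_lt(mean_pairwise_r2(ind, 1:10), 0.01)
  ld <- simulate_genotypes(simulation_config(n_samples = 4000, n_snps = 10,
                                             n_linear = 2,
                                             n_epistatic_pairs = 0,
                                             maf_range = c(0.1, 0.5),
                                             ld_block_size = 10, ld_rho = 0.8,
                                             seed = 2))
  expect_gt(mean_pairwise_r2(ld, 1:10), 0.2)
})

test_that("noiseless linear phenotype is exactly linear in causal SNPs", {
  sim <- quick_sim(n = 500, p = 50, n_linear = 8, n_pairs = 0,
                   w_l = 1, w_ep = 0, w_eps = 0, seed = 5)
  x <- sim$dataset$genotypes[, sim$truth$linear_snps$snp]
  fit <- stats::lm(sim$dataset$phenotype ~ x)
  expect_gt(summary(fit)$r.squared, 1 - 1e-9)
})

test_that("epistatic events contribute beta exactly on the indicator", {
  sim <- quick_sim(n = 3000, p = 40, n_linear = 0, n_pairs = 3,
                   w_l = 0, w_ep = 0.8, w_eps = 0.2, seed = 8)
  tr <- sim$truth
  g <- sim$dataset$genotypes
  # reconstruct the raw epistatic sum from the recorded truth
  y_ep_raw <- rowSums(vapply(seq_len(nrow(tr$epistatic_pairs)), function(k) {
    p <- tr$epistatic_pairs[k, ]
    p$beta * ((g[, p$snp_a] == p$g_a) & (g[, p$snp_b] == p$g_b))
  }, numeric(nrow(g))))
  expect_gt(abs(stats::cor(y_ep_raw, tr$component_vectors[, "y_ep"])),
            1 - 1e-12)
  # a single pair: samples matching both genotype values get beta, others 0
  p1 <- tr$epistatic_pairs[1, ]
  hit <- (g[, p1$snp_a] == p1$g_a) & (g[, p1$snp_b] == p1$g_b)
  expect_true(any(hit))
  contrib <- p1$beta * hit
  expect_identical(unique(contrib[!hit]), 0)
  expect_equal(unique(contrib[hit]), p1$beta)
})

test_that("component variance shares match the configured weights", {
  sim <- quick_sim(n = 10000, p = 100, n_linear = 20, n_pairs = 0,
                   w_l = 0.8, w_ep = 0, w_eps = 0.2, seed = 3)
  y <- sim$dataset$phenotype
  noise_share <- 0.2 * stats::var(sim$truth$component_vectors[, "y_eps"]) /
    stats::var(y)
  expect_equal(noise_share, 0.2, tolerance = 0.02 / 0.2)
  lm_fit <- stats::lm(y ~ sim$dataset$genotypes[, sim$truth$linear_snps$snp])
  expect_equal(summary(lm_fit)$r.squared, 0.8, tolerance = 0.03)
})

test_that("causal SNP sets are disjoint and in range", {
  for (seed in 1:3) {
    sim <- quick_sim(n = 200, p = 60, n_linear = 15, n_pairs = 10,
                     seed = seed)
    lin <- sim$truth$linear_snps$snp
    ep <- c(sim$truth$epistatic_pairs$snp_a, sim$truth$epistatic_pairs$snp_b)
    expect_length(intersect(lin, ep), 0)
    expect_length(unique(ep), 20)
    expect_true(all(c(lin, ep) %in% seq_len(60)))
  }
})

test_that("covariate-free phenotypes are independent of covariates", {
  sim <- simulate_dataset(simulation_config(
    n_samples = 10000, n_snps = 50, n_linear = 10, n_epistatic_pairs = 0,
    w_l = 0.8, w_ep = 0, w_eps = 0.2, n_covariates = 3,
    covariate_effect = "none", seed = 6))
  cors <- abs(stats::cor(sim$dataset$phenotype, sim$dataset$covariates))
  expect_true(all(cors < 0.05))
  expect_equal(mean(sim$dataset$covariates[, "sex"]), 0.5, tolerance = 0.04)
})

test_that("nonlinear covariate effects favor depth-2 trees over the lasso", {
  gaps <- vapply(1:3, function(seed) {
    sim <- simulate_dataset(simulation_config(
      n_samples = 5000, n_snps = 10, n_linear = 0, n_epistatic_pairs = 0,
      w_l = 0.7, w_ep = 0, w_eps = 0.3, n_covariates = 3,
      covariate_effect = "nonlinear", seed = seed))
    ds <- sim$dataset
    # covariates-only models: drop the SNPs from the feature set
    sp <- split_list(ds)
    cov_only <- function(d) { d$genotypes <- d$genotypes[, 1, drop = FALSE]; d }
    tr <- cov_only(sp$train); va <- cov_only(sp$validation)
    xgb <- fit_model(tr, va, model_spec("boosted", depth = 2, seed = seed),
                     snp_idx = integer(0))
    las <- fit_model(tr, va, model_spec("l1_linear", seed = seed),
                     snp_idx = integer(0))
    xgb$validation_metric - las$validation_metric
  }, numeric(1))
  expect_gt(stats::median(gaps), 0)
})

test_that("binary phenotypes hit the target prevalence", {
  sim <- quick_sim(n = 4000, p = 50, n_linear = 10, n_pairs = 0,
                   w_l = 0.8, w_ep = 0, w_eps = 0.2, binary = TRUE,
                   prevalence = 0.15, seed = 4)
  expect_equal(mean(sim$dataset$phenotype), 0.15, tolerance = 0.01)
})

test_that("truth serializes to JSON", {
  sim <- quick_sim(n = 100, p = 30, n_linear = 5, n_pairs = 2, seed = 1)
  path <- tempfile(fileext = ".json")
  write_truth_json(sim$truth, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$linear_snps$snp, sim$truth$linear_snps$snp)
  expect_equal(back$epistatic_pairs$beta, sim$truth$epistatic_pairs$beta)
})
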