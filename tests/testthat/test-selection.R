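test_that("window partition covers every SNP exactly once in all orders", {
  fw <- partition_windows(25, 10, "forward")
  expect_identical(fw$windows, list(1:10, 11:20, 21:25))
  bw <- partition_windows(25, 10, "backward")
  expect_identical(bw$windows, list(21:25, 11:20, 1:10))
  sh1 <- partition_windows(25, 10, "shuffled", shuffle_seed = 7)
  sh2 <- partition_windows(25, 10, "shuffled", shuffle_seed = 7)
  expect_identical(sh1$windows, sh2$windows)
  for (plan in list(fw, bw, sh1)) {
    flat <- unlist(plan$windows)
    expect_setequal(flat, 1:25)
    expect_identical(length(flat), 25L)
    expect_true(all(lengths(plan$windows) <= 10))
  }
  expect_false(identical(sh1$windows, fw$windows))
})

test_that("single-window selection equals a plain boosted fit", {
  sim <- quick_sim(n = 1500, p = 60, n_linear = 8, n_pairs = 4, seed = 2)
  ds <- sim$dataset
  one <- run_window_selection(ds, partition_windows(60, 60, "forward"),
                              fast_params(), use_covariates = FALSE)
  same <- run_window_selection(ds, partition_windows(60, 500, "forward"),
                               fast_params(), use_covariates = FALSE)
  expect_identical(one$importance, same$importance)
  expect_identical(length(one$chain_predictions), 1L)
})

test_that("selection recovers causal SNPs and respects the chain", {
  sim <- quick_sim(n = 3000, p = 100, n_linear = 15, n_pairs = 0,
                   w_l = 0.8, w_ep = 0, w_eps = 0.2, seed = 3)
  ds <- sim$dataset
  sres <- run_window_selection(ds, partition_windows(100, 25, "forward"),
                               fast_params(), use_covariates = FALSE)
  expect_identical(unname(sres$window_of[1]), 1L)
  expect_identical(unname(sres$window_of[100]), 4L)
  # importance defined everywhere; never-split SNPs are exactly 0
  expect_length(sres$importance, 100)
  expect_true(all(sres$importance >= 0))
  top <- select_top_snps(sres, 30)
  expect_gt(mean(sim$truth$linear_snps$snp %in% top), 0.7)
  # chain validation metric improves as windows accumulate signal
  expect_gt(utils::tail(sres$validation_metric, 1),
            sres$validation_metric[1] - 0.02)
})

test_that("forward and backward orders differ in membership, not accuracy", {
  sim <- quick_sim(n = 3000, p = 100, n_linear = 15, n_pairs = 0,
                   w_l = 0.8, w_ep = 0, w_eps = 0.2, seed = 4)
  ds <- sim$dataset
  fw <- run_window_selection(ds, partition_windows(100, 25, "forward"),
                             fast_params(), use_covariates = FALSE)
  bw <- run_window_selection(ds, partition_windows(100, 25, "backward"),
                             fast_params(), use_covariates = FALSE)
  expect_false(identical(select_top_snps(fw, 30), select_top_snps(bw, 30)))
  sp <- split_list(ds)
  accs <- vapply(list(fw, bw), function(sres) {
    m <- fit_model(sp$train, sp$validation, model_spec("boosted", depth = 2),
                   snp_idx = select_top_snps(sres, 30),
                   use_covariates = FALSE)
    r_squared(sp$test$phenotype, predict(m, sp$test))
  }, numeric(1))
  se <- se_subsampling(sp$test$phenotype, sp$test$phenotype * 0, "r2",
                       seed = 1)
  se <- max(se, 0.02)
  expect_lt(abs(accs[1] - accs[2]), 3 * max(se, 0.05))
})

test_that("top-k selection breaks ties by genome order and pads with warning", {
  expect_identical(select_top_snps(c(0.5, 0.1, 0.9), 2), c(3L, 1L))
  expect_identical(select_top_snps(rep(1, 5), 3), 1:3)
  expect_identical(select_top_snps(c(0.5, 0.1, 0.9), 3), c(3L, 1L, 2L))
  expect_warning(out <- select_top_snps(c(0, 0.3, 0), 2), "positive")
  expect_identical(out, c(2L, 1L))
  expect_error(select_top_snps(c(1, 2), 3), "k must be")
})

test_that("gwas_select ranks a planted strong SNP first", {
  set.seed(10)
  g <- matrix(sample(0:2, 2000 * 20, TRUE), 2000, 20)
  y <- 2 * g[, 7] + stats::rnorm(2000, 0, 0.5)
  ds <- tiny_dataset(g, phenotype = y,
                     split = rep(c("train", "validation", "test"),
                                 c(1600, 200, 200)))
  res <- gwas_select(ds, 5)
  expect_identical(res$snps[1], 7L)
  expect_identical(gwas_select(ds, 0)$snps, integer(0))
})

test_that("gwas p-values are uniform under the null and 1 for monomorphic SNPs", {
  set.seed(11)
  g <- matrix(sample(0:2, 5000 * 1000, TRUE, prob = c(.49, .42, .09)),
              5000, 1000)
  g[, 13] <- 1L
  y <- stats::rnorm(5000)
  ds <- tiny_dataset(g, phenotype = y,
                     split = rep(c("train", "validation", "test"),
                                 c(4000, 500, 500)))
  res <- gwas_select(ds, 1000)
  expect_identical(unname(res$p_values[13]), 1)
  expect_identical(res$snps[1000], 13L)  # never before polymorphic SNPs
  ks <- stats::ks.test(res$p_values[-13], "punif")$statistic
  expect_lt(unname(ks), 0.05)
})

test_that("binary gwas score test finds a planted SNP", {
  set.seed(12)
  g <- matrix(sample(0:2, 3000 * 15, TRUE), 3000, 15)
  cov <- matrix(stats::rnorm(3000), ncol = 1, dimnames = list(NULL, "age"))
  y <- stats::rbinom(3000, 1, stats::plogis(-0.5 + g[, 4] + 0.5 * cov[, 1]))
  ds <- tiny_dataset(g, phenotype = y, kind = "binary", covariates = cov,
                     split = rep(c("train", "validation", "test"),
                                 c(2400, 300, 300)))
  res <- gwas_select(ds, 3)
  expect_identical(res$snps[1], 4L)
})

test_that("selection results serialize as ranked TSV", {
  sim <- quick_sim(n = 800, p = 30, n_linear = 5, n_pairs = 0,
                   w_l = 0.8, w_ep = 0, w_eps = 0.2, seed = 5)
  sres <- run_window_selection(sim$dataset,
                               partition_windows(30, 15, "forward"),
                               fast_params(), use_covariates = FALSE)
  path <- tempfile(fileext = ".tsv")
  write_selection_tsv(sres, path)
  tab <- read.delim(path)
  expect_identical(nrow(tab), 30L)
  expect_identical(sort(tab$rank), 1:30)
  expect_identical(tab$snp_id[tab$rank == 1],
                   sim$dataset$map$snp_id[select_top_snps(sres, 1)])
})
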