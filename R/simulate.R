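#' Simulation configuration
#'
#' Describes a synthetic genotype/phenotype study: biallelic SNPs with
#' configurable minor allele frequencies and optional linkage-disequilibrium
#' blocks, a phenotype composed of linear SNP effects, pairwise epistatic
#' indicator effects and Gaussian noise, plus optional covariates.
#'
#' The phenotype is `y = sqrt(w_l) y_l + sqrt(w_ep) y_ep + sqrt(w_eps) y_eps`
#' with each component standardized to unit variance before weighting, so the
#' weights are the variance shares of the components.
#'
#' @param n_samples,n_snps Problem dimensions.
#' @param maf_range Minor-allele-frequency range; each SNP's frequency is
#'   drawn uniformly from it. Default `(0.005, 0.5)`, the common-variant
#'   spectrum above a 0.5% MAF filter.
#' @param ld_block_size SNPs per LD block (1 = independent SNPs).
#' @param ld_rho Latent haplotype correlation within a block, in `[0, 1)`.
#' @param n_linear Number of linearly causal SNPs.
#' @param n_epistatic_pairs Number of causal epistatic SNP pairs.
#' @param w_l,w_ep,w_eps Variance weights of the linear, epistatic and noise
#'   components; must be nonnegative and sum to 1.
#' @param n_covariates Number of simulated covariates (the first is a binary
#'   sex-like column, the rest standard normal).
#' @param covariate_effect `"none"`, `"linear"` or `"nonlinear"` (nonlinear
#'   adds a squared transform of one covariate).
#' @param gene_covariate_pairs Number of SNP-by-covariate interaction terms.
#' @param binary If `TRUE`, the phenotype is dichotomized by a liability
#'   threshold at `prevalence`.
#' @param prevalence Case fraction for binary phenotypes.
#' @param seed Integer seed; all three simulation stages are deterministic
#'   given the seed.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_samples = 10000L, n_snps = 1000L,
                              maf_range = c(0.005, 0.5),
                              ld_block_size = 1L, ld_rho = 0,
                              n_linear = 100L, n_epistatic_pairs = 50L,
                              w_l = 0.8, w_ep = 0, w_eps = 0.2,
                              n_covariates = 0L,
                              covariate_effect = c("none", "linear",
                                                   "nonlinear"),
                              gene_covariate_pairs = 0L,
                              binary = FALSE, prevalence = 0.1,
                              seed = 1L) {
  covariate_effect <- match.arg(covariate_effect)
  if (n_samples < 2 || n_snps < 1) stop_input("bad dimensions")
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2])
    stop_input("maf_range must be within (0, 0.5]")
  if (ld_block_size < 1) stop_input("ld_block_size must be >= 1")
  if (ld_rho < 0 || ld_rho >= 1) stop_input("ld_rho must be in [0, 1)")
  if (abs(w_l + w_ep + w_eps - 1) > 1e-9)
    stop_input("w_l + w_ep + w_eps must sum to 1")
  if (min(w_l, w_ep, w_eps) < 0) stop_input("component weights must be >= 0")
  if (2 * n_epistatic_pairs + n_linear > n_snps)
    stop_input("causal SNP sets exceed n_snps")
  if (w_ep > 0 && n_epistatic_pairs == 0 && gene_covariate_pairs == 0)
    stop_input("w_ep > 0 requires epistatic pairs or gene-covariate terms")
  if (gene_covariate_pairs > 0 && n_covariates == 0)
    stop_input("gene_covariate_pairs > 0 requires covariates")
  if (covariate_effect != "none" && n_covariates < 1)
    stop_input("covariate_effect requires n_covariates >= 1")
  structure(list(n_samples = as.integer(n_samples),
                 n_snps = as.integer(n_snps), maf_range = maf_range,
                 ld_block_size = as.integer(ld_block_size), ld_rho = ld_rho,
                 n_linear = as.integer(n_linear),
                 n_epistatic_pairs = as.integer(n_epistatic_pairs),
                 w_l = w_l, w_ep = w_ep, w_eps = w_eps,
                 n_covariates = as.integer(n_covariates),
                 covariate_effect = covariate_effect,
                 gene_covariate_pairs = as.integer(gene_covariate_pairs),
                 binary = binary, prevalence = prevalence,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Simulate a genotype matrix
#'
#' Each SNP's allele frequency is drawn uniformly from `maf_range`. Within an
#' LD block, the two haplotypes of every sample are thresholded latent
#' Gaussians sharing a block factor with correlation `ld_rho`, so genotypes
#' obey Hardy-Weinberg proportions per SNP while neighbouring SNPs are
#' correlated; `ld_block_size = 1` gives independent SNPs.
#'
#' @param config A [simulation_config()].
#' @return A [genotype_dataset()] with no phenotype; the drawn allele
#'   frequencies are attached as attribute `"maf"`.
#' @export
simulate_genotypes <- function(config) {
  with_seed(config$seed, {
    n <- config$n_samples; p <- config$n_snps
    maf <- stats::runif(p, config$maf_range[1], config$maf_range[2])
    thr <- stats::qnorm(maf)
    g <- matrix(0L, n, p)
    blocks <- split(seq_len(p), (seq_len(p) - 1L) %/% config$ld_block_size)
    rho <- config$ld_rho
    for (blk in blocks) {
      acc <- matrix(0L, n, length(blk))
      for (h in 1:2) {  # two independent haplotypes per sample
        shared <- stats::rnorm(n)
        z <- sqrt(rho) * shared +
          sqrt(1 - rho) * matrix(stats::rnorm(n * length(blk)), n)
        acc <- acc + (z < rep(thr[blk], each = n))
      }
      g[, blk] <- acc
    }
    map <- data.frame(snp_id = sprintf("snp%05d", seq_len(p)),
                      chrom = 1L, pos = seq_len(p) * 1000L,
                      a1 = "A", a2 = "B")
    ds <- genotype_dataset(g, map, sprintf("s%06d", seq_len(n)))
    attr(ds, "maf") <- maf
    ds
  })
}

#' Simulate covariates
#'
#' Draws `n_covariates` covariate columns: a binary sex-like column
#' (Bernoulli 0.5) followed by standard normal columns. The covariate
#' phenotype contributions themselves (linear, nonlinear, gene-covariate
#' interaction terms) are materialized later by [simulate_phenotype()], which
#' records them in the returned truth.
#'
#' @param genotypes A [genotype_dataset()].
#' @param config A [simulation_config()] with `n_covariates >= 1`.
#' @return The dataset with `$covariates` set (`sex`, `cov2`, `cov3`, ...).
#' @export
simulate_covariates <- function(genotypes, config) {
  if (config$n_covariates < 1) stop_input("n_covariates must be >= 1")
  with_seed(config$seed + 1L, {
    n <- nrow(genotypes$genotypes)
    covs <- matrix(stats::rnorm(n * config$n_covariates), n)
    covs[, 1] <- stats::rbinom(n, 1, 0.5)
    colnames(covs) <- c("sex",
                        if (config$n_covariates > 1)
                          paste0("cov", 2:config$n_covariates))
    genotypes$covariates <- covs
    genotypes
  })
}

#' Simulate a phenotype with linear, epistatic and noise components
#'
#' Builds `y_l` as a weighted sum of `n_linear` causal genotype columns with
#' standard normal effect sizes, `y_ep` as a sum of pairwise epistatic
#' indicator events `beta * 1{g_a = v_a} * 1{g_b = v_b}` over
#' `n_epistatic_pairs` disjoint SNP pairs, and `y_eps` as standard normal
#' noise. Covariate effects, when configured, enter `y_l` (linear/nonlinear
#' single-covariate terms) and `y_ep` (gene-covariate interaction terms)
#' before standardization. Each component is standardized to unit sample
#' variance and combined as
#' `y = sqrt(w_l) y_l + sqrt(w_ep) y_ep + sqrt(w_eps) y_eps`, so the
#' component variance contributions equal the configured weights.
#'
#' Epistatic genotype combinations `(v_a, v_b)` are drawn uniformly from the
#' nine joint genotype values and redrawn while their Hardy-Weinberg
#' population frequency is below 0.5%, so every event is observable.
#'
#' @param genotypes A [genotype_dataset()] (with covariates attached when the
#'   config requests covariate effects).
#' @param config A [simulation_config()].
#' @return A list with `dataset` (phenotype filled in) and `truth` (a
#'   `simulation_truth` list: `linear_snps`, `epistatic_pairs`,
#'   `covariate_effects`, `gene_covariate_terms`, component vectors `y_l`,
#'   `y_ep`, `y_eps`, and for binary phenotypes the liability threshold).
#' @export
simulate_phenotype <- function(genotypes, config) {
  n <- nrow(genotypes$genotypes); p <- ncol(genotypes$genotypes)
  if (config$n_linear + 2 * config$n_epistatic_pairs > p)
    stop_input("causal SNP counts exceed available SNPs")
  if (config$w_ep > 0 && config$n_epistatic_pairs == 0 &&
      config$gene_covariate_pairs == 0)
    stop_input("w_ep > 0 requires epistatic pairs or gene-covariate terms")
  maf <- attr(genotypes, "maf") %||% (colMeans(genotypes$genotypes) / 2)
  g <- genotypes$genotypes
  with_seed(config$seed + 2L, {
    causal <- sample.int(p, config$n_linear + 2L * config$n_epistatic_pairs)
    lin_idx <- sort(causal[seq_len(config$n_linear)])
    ep_idx <- causal[config$n_linear + seq_len(2L * config$n_epistatic_pairs)]

    beta_l <- stats::rnorm(config$n_linear)
    y_l <- if (config$n_linear > 0)
      as.numeric(g[, lin_idx, drop = FALSE] %*% beta_l) else numeric(n)

    # Hardy-Weinberg genotype frequencies for combination resampling
    hw <- function(pj) c((1 - pj)^2, 2 * pj * (1 - pj), pj^2)
    pairs <- NULL
    y_ep <- numeric(n)
    if (config$n_epistatic_pairs > 0) {
      a <- ep_idx[seq_len(config$n_epistatic_pairs)]
      b <- ep_idx[-seq_len(config$n_epistatic_pairs)]
      va <- vb <- integer(config$n_epistatic_pairs)
      beta_ep <- stats::rnorm(config$n_epistatic_pairs)
      for (k in seq_len(config$n_epistatic_pairs)) {
        fa <- hw(maf[a[k]]); fb <- hw(maf[b[k]])
        repeat {
          va[k] <- sample(0:2, 1); vb[k] <- sample(0:2, 1)
          if (fa[va[k] + 1L] * fb[vb[k] + 1L] >= 0.005) break
        }
        y_ep <- y_ep + beta_ep[k] *
          ((g[, a[k]] == va[k]) & (g[, b[k]] == vb[k]))
      }
      pairs <- data.frame(snp_a = a, snp_b = b, g_a = va, g_b = vb,
                          beta = beta_ep)
    }

    cov_eff <- NULL; gene_cov <- NULL
    if (config$covariate_effect != "none") {
      cv <- genotypes$covariates
      if (is.null(cv)) stop_input("covariate effects requested but dataset has no covariates")
      beta_c <- stats::rnorm(ncol(cv))
      y_l <- y_l + as.numeric(scale(cv) %*% beta_c)
      cov_eff <- data.frame(covariate = colnames(cv), beta = beta_c,
                            form = "linear")
      if (config$covariate_effect == "nonlinear") {
        j <- if (ncol(cv) > 1) 2L else 1L  # first continuous column
        bq <- stats::rnorm(1)
        y_l <- y_l + bq * as.numeric(scale(cv[, j]^2))
        cov_eff <- rbind(cov_eff,
                         data.frame(covariate = colnames(cv)[j], beta = bq,
                                    form = "squared"))
      }
    }
    if (config$gene_covariate_pairs > 0) {
      cv <- genotypes$covariates
      if (is.null(cv)) stop_input("gene_covariate_pairs requires covariates")
      free <- setdiff(seq_len(p), causal)
      gsnp <- sample(free, config$gene_covariate_pairs)
      gcov <- sample(ncol(cv), config$gene_covariate_pairs, replace = TRUE)
      gv <- integer(config$gene_covariate_pairs)
      gb <- stats::rnorm(config$gene_covariate_pairs)
      for (k in seq_len(config$gene_covariate_pairs)) {
        fa <- hw(maf[gsnp[k]])
        repeat {
          gv[k] <- sample(0:2, 1)
          if (fa[gv[k] + 1L] >= 0.005) break
        }
        y_ep <- y_ep + gb[k] * (g[, gsnp[k]] == gv[k]) * cv[, gcov[k]]
      }
      gene_cov <- data.frame(snp = gsnp, covariate = colnames(cv)[gcov],
                             g = gv, beta = gb)
    }

    y_eps <- stats::rnorm(n)
    std <- function(v) {
      s <- stats::sd(v)
      if (s > 0) (v - mean(v)) / s else v * 0
    }
    comp <- cbind(y_l = std(y_l), y_ep = std(y_ep), y_eps = std(y_eps))
    w <- c(config$w_l, config$w_ep, config$w_eps)
    y <- as.numeric(comp %*% sqrt(w))

    thr <- NULL
    if (config$binary) {
      thr <- stats::quantile(y, 1 - config$prevalence)
      y <- as.integer(y > thr)
    }
    genotypes$phenotype <- y
    genotypes$phenotype_kind <- if (config$binary) "binary" else "quantitative"
    truth <- structure(list(
      linear_snps = data.frame(snp = lin_idx, beta = beta_l),
      epistatic_pairs = pairs,
      covariate_effects = cov_eff,
      gene_covariate_terms = gene_cov,
      component_vectors = comp,
      weights = w, liability_threshold = thr),
      class = "simulation_truth")
    list(dataset = genotypes, truth = truth)
  })
}

#' Simulate a complete study dataset
#'
#' Convenience wrapper chaining [simulate_genotypes()],
#' [simulate_covariates()] (when configured), [simulate_phenotype()] and
#' [make_splits()].
#'
#' @param config A [simulation_config()].
#' @param split A [split_spec()], or `NULL` to skip splitting.
#' @return A list with `dataset` and `truth`.
#' @export
simulate_dataset <- function(config,
                             split = split_spec(seed = config$seed)) {
  ds <- simulate_genotypes(config)
  if (config$n_covariates > 0) ds <- simulate_covariates(ds, config)
  sim <- simulate_phenotype(ds, config)
  if (!is.null(split)) sim$dataset <- make_splits(sim$dataset, split)
  sim
}

#' Serialize simulation ground truth as JSON
#'
#' @param truth A `simulation_truth` object from [simulate_phenotype()].
#' @param path Output path.
#' @export
write_truth_json <- function(truth, path) {
  out <- list(linear_snps = truth$linear_snps,
              epistatic_pairs = truth$epistatic_pairs,
              covariate_effects = truth$covariate_effects,
              gene_covariate_terms = truth$gene_covariate_terms,
              weights = truth$weights,
              liability_threshold = truth$liability_threshold)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
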