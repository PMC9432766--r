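# Shared fixture builders; everything is generated in code at test time.

# Tiny hand-specified dataset: n samples x p SNPs with optional missing calls.
tiny_dataset <- function(g, phenotype = NULL, kind = "quantitative",
                         covariates = NULL, split = NULL) {
  g <- as.matrix(g)
  map <- data.frame(snp_id = paste0("rs", seq_len(ncol(g))), chrom = 1L,
                    pos = seq_len(ncol(g)) * 100L, a1 = "A", a2 = "B")
  genotype_dataset(g, map, paste0("s", seq_len(nrow(g))),
                   phenotype = phenotype, phenotype_kind = kind,
                   covariates = covariates, split = split)
}

# Small simulated quantitative study used across tests.
quick_sim <- function(n = 2000, p = 100, n_linear = 10, n_pairs = 5,
                      w_l = 0.6, w_ep = 0.2, w_eps = 0.2, seed = 1,
                      ...) {
  simulate_dataset(simulation_config(
    n_samples = n, n_snps = p, n_linear = n_linear,
    n_epistatic_pairs = n_pairs, w_l = w_l, w_ep = w_ep, w_eps = w_eps,
    seed = seed, ...))
}

split_list <- function(ds)
  lapply(c(train = "train", validation = "validation", test = "test"),
         function(s) get_split(ds, s))

fast_params <- function(...) learner_params(max_trees = 300L, ...)
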