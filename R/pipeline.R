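#' Build and validate a pipeline configuration
#'
#' A declarative record of one end-to-end experiment: data source (PLINK
#' paths or a simulation), covariate policy, selection method, model list,
#' ensembling and metrics. Accepts a YAML file path or a nested list;
#' validation happens before any compute.
#'
#' @param config Path to a YAML file or a list with entries:
#'   `data` (either `plink: {bed, bim, fam, phenotype_table}` or
#'   `simulation:` with [simulation_config()] fields), `phenotype_kind`,
#'   `min_maf`, `split` ([split_spec()] fields), `covariate_policy`
#'   (`none`, `sex_only`, `sex_age_pcs`, `full`), `n_pcs`, `selection`
#'   (`method` = `windowed`/`gwas`, `window_size`, `order`, `top_k`,
#'   `depth`, `alpha`), `models` (list of [model_spec()] field lists, each
#'   with a `name`), `ensemble` (`enabled`, `grid_resolution`), `metrics`,
#'   `outdir`, `seed`.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop_input("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  defaults <- list(
    phenotype_kind = "quantitative", min_maf = 0,
    split = list(train_fraction = 0.8, validation_fraction = 0.1,
                 test_fraction = 0.1),
    covariate_policy = "none", n_pcs = 10L,
    selection = list(method = "windowed", window_size = 10000L,
                     order = "forward", top_k = 300L, depth = 2L,
                     alpha = 15),
    models = list(list(name = "xgb2", learner = "boosted", depth = 2L)),
    ensemble = list(enabled = FALSE, grid_resolution = 0.01),
    metrics = NULL, outdir = NULL, seed = 1L)
  cfg <- defaults
  for (key in names(config)) {
    # shallow-merge named sub-lists (split, selection, ensemble); replace
    # everything else wholesale (models is an unnamed list)
    if (key %in% c("split", "selection", "ensemble") &&
        is.list(config[[key]])) {
      cfg[[key]][names(config[[key]])] <- config[[key]]
    } else cfg[[key]] <- config[[key]]
  }
  if (is.null(cfg$data) ||
      is.null(cfg$data$plink) == is.null(cfg$data$simulation))
    stop_input("config$data must have exactly one of plink/simulation")
  if (!is.null(cfg$data$plink)) {
    for (f in unlist(cfg$data$plink[c("bed", "bim", "fam")]))
      if (!file.exists(f)) stop_input("referenced file missing: ", f)
  }
  if (!cfg$covariate_policy %in% c("none", "sex_only", "sex_age_pcs", "full"))
    stop_input("unknown covariate_policy: ", cfg$covariate_policy)
  if (!cfg$selection$method %in% c("windowed", "gwas"))
    stop_input("selection$method must be windowed or gwas")
  for (m in cfg$models)
    if (is.null(m$name)) stop_input("every model needs a name")
  do.call(split_spec, c(cfg$split, list(seed = cfg$seed)))  # validates
  structure(cfg, class = "pipeline_config")
}

write_stage <- function(outdir, name, writer) {
  if (is.null(outdir)) return(invisible(NULL))
  path <- file.path(outdir, name)
  writer(path)
  path
}

#' Run the full pipeline
#'
#' Executes simulate/load -> MAF filter -> split -> covariate policy ->
#' selection -> model fits -> ensemble -> evaluation, persisting every
#' intermediate (selected SNPs, predictions, weights, metric reports and a
#' manifest with content hashes) when `outdir` is set. Deterministic given
#' the config seed.
#'
#' @param config A [pipeline_config()] (or YAML path / list).
#' @param nthread Learner threads.
#' @return A report list: `dataset` sizes, `selection`, `models` (validation
#'   and test metric reports per model), `ensemble`, `manifest`.
#' @export
run_pipeline <- function(config, nthread = 1L) {
  cfg <- if (inherits(config, "pipeline_config")) config
         else pipeline_config(config)
  outdir <- cfg$outdir
  if (!is.null(outdir)) dir.create(outdir, recursive = TRUE,
                                   showWarnings = FALSE)
  files <- character(0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_input("pipeline stage '", name, "' failed: ",
                 conditionMessage(e)))
  }

  truth <- NULL
  if (!is.null(cfg$data$simulation)) {
    sim_cfg <- do.call(simulation_config,
                       utils::modifyList(cfg$data$simulation,
                                         list(seed = cfg$seed)))
    sim <- stage("simulate", simulate_dataset(
      sim_cfg, do.call(split_spec, c(cfg$split, list(seed = cfg$seed)))))
    ds <- sim$dataset; truth <- sim$truth
  } else {
    ds <- stage("load", load_plink(cfg$data$plink$bed, cfg$data$plink$bim,
                                   cfg$data$plink$fam,
                                   cfg$data$plink$phenotype_table,
                                   phenotype_kind = cfg$phenotype_kind))
    if (cfg$min_maf > 0) ds <- stage("maf_filter", filter_maf(ds, cfg$min_maf))
    ds <- stage("split", make_splits(
      ds, do.call(split_spec, c(cfg$split, list(seed = cfg$seed)))))
  }
  if (cfg$covariate_policy %in% c("sex_age_pcs", "full"))
    ds <- stage("pca", add_pc_covariates(ds, cfg$n_pcs))
  use_cov <- cfg$covariate_policy != "none" && !is.null(ds$covariates)

  sel <- cfg$selection
  top_k <- min(sel$top_k, ncol(ds$genotypes))
  if (sel$method == "windowed") {
    plan <- partition_windows(ncol(ds$genotypes), sel$window_size, sel$order,
                              shuffle_seed = cfg$seed)
    sres <- stage("select", run_window_selection(
      ds, plan, learner_params(depth = sel$depth, alpha = sel$alpha,
                               nthread = nthread, seed = cfg$seed),
      use_covariates = use_cov))
    chosen <- select_top_snps(sres, top_k)
    files <- c(files, write_stage(outdir, "selection.tsv",
                                  function(p) write_selection_tsv(sres, p)))
  } else {
    g <- stage("select", gwas_select(ds, top_k, use_covariates = use_cov))
    sres <- g
    chosen <- g$snps
  }

  splits <- lapply(c(train = "train", validation = "validation",
                     test = "test"), function(s) get_split(ds, s))
  models <- list(); preds_va <- list(); preds_te <- list()
  for (m in cfg$models) {
    spec <- do.call(model_spec,
                    c(m[setdiff(names(m), "name")], list(seed = cfg$seed)))
    fit <- stage(paste0("fit:", m$name),
                 fit_model(splits$train, splits$validation, spec,
                           snp_idx = chosen, use_covariates = use_cov,
                           nthread = nthread))
    preds_va[[m$name]] <- predict(fit, splits$validation)
    preds_te[[m$name]] <- predict(fit, splits$test)
    models[[m$name]] <- fit
    if (!is.null(outdir)) {
      pfx <- file.path(outdir, paste0("model_", m$name))
      save_model(fit, pfx)
      files <- c(files, paste0(pfx, ".json"),
                 Filter(file.exists, paste0(pfx, ".model.ubj")))
    }
  }

  metric <- if (ds$phenotype_kind == "binary") "auc" else "r2"
  reports <- lapply(names(models), function(nm)
    list(validation = models[[nm]]$validation_metric,
         test = metric_report(splits$test$phenotype, preds_te[[nm]], metric,
                              seed = cfg$seed)))
  names(reports) <- names(models)

  ens <- NULL
  if (isTRUE(cfg$ensemble$enabled) && length(models) >= 2) {
    w <- stage("ensemble", fit_ensemble_weights(
      preds_va, splits$validation$phenotype, metric,
      cfg$ensemble$grid_resolution))
    comb <- apply_weights(w, preds_te)
    ens <- list(weights = w,
                test = metric_report(splits$test$phenotype, comb, metric,
                                     seed = cfg$seed))
    files <- c(files, write_stage(outdir, "ensemble_weights.json",
      function(p) jsonlite::write_json(list(weights = w$weights,
        validation_metric = w$validation_metric), p, auto_unbox = TRUE,
        digits = NA)))
  }

  if (!is.null(outdir)) {
    files <- c(files, write_stage(outdir, "predictions_test.tsv", function(p)
      utils::write.table(data.frame(sample_id = splits$test$sample_ids,
                                    as.data.frame(preds_te)),
                         p, sep = "\t", quote = FALSE, row.names = FALSE)))
    files <- c(files, write_stage(outdir, "metrics.json", function(p)
      jsonlite::write_json(lapply(reports, function(r)
        list(validation = r$validation, test = unclass(r$test))), p,
        auto_unbox = TRUE, digits = NA, null = "null")))
    files <- c(files, write_stage(outdir, "resolved_config.yaml", function(p)
      yaml::write_yaml(unclass(cfg), p)))
    manifest <- data.frame(file = basename(files),
                           md5 = unname(tools::md5sum(files)))
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(n_samples = nrow(ds$genotypes), n_snps = ncol(ds$genotypes),
       selection = sres, selected_snps = chosen, models = models,
       reports = reports, ensemble = ens, truth = truth,
       manifest = if (!is.null(outdir)) files)
}

#' Fraction of truth SNPs recovered in the top-k importance ranking
#'
#' @param result A `selection_result` (or importance vector).
#' @param truth_snps Integer indices of the causal SNPs to look for.
#' @param k Ranking cutoff (default 300, the convention used for epistasis
#'   detection).
#' @return Named vector: `snp_fraction` (fraction of `truth_snps` ranked in
#'   the top `k`).
#' @export
detection_fraction <- function(result, truth_snps, k = 300L) {
  top <- select_top_snps(result, k)
  mean(truth_snps %in% top)
}

#' Simulation study of epistasis detection and prediction accuracy
#'
#' For each epistatic weight `w_ep` and seed: simulates a quantitative
#' phenotype (noise weight fixed at `w_eps`, linear weight
#' `1 - w_ep - w_eps`), runs windowed boosted selection, fits a depth-2
#' boosted model on the top-`top_k` selected SNPs and an L1 linear baseline
#' on all SNPs, and scores epistasis recovery against the simulation truth.
#' The reference design uses 100K samples, 1K SNPs, 100 linear SNPs and 50
#' epistatic pairs; scale `n_samples` down for quick runs.
#'
#' @param w_ep_grid Epistatic weights to sweep (within `[0, 0.8]`).
#' @param seeds Integer vector of simulation seeds.
#' @param n_samples,n_snps,n_linear,n_epistatic_pairs,w_eps Design knobs.
#' @param window_size Selection window size.
#' @param top_k Importance cutoff for "found" SNPs and for the prediction
#'   feature set.
#' @param nthread Learner threads.
#' @param out_tsv Optional path for a per-cell TSV (mean and SD over seeds).
#' @return Data frame with one row per `(w_ep, seed)`: `lasso_r2`, `xgb_r2`,
#'   `frac_epistatic_snps`, `frac_epistatic_pairs`, `frac_linear_snps`.
#' @export
run_simulation_study <- function(w_ep_grid = c(0, 0.2, 0.4, 0.6, 0.8),
                                seeds = 1:3,
                                n_samples = 100000L, n_snps = 1000L,
                                n_linear = 100L, n_epistatic_pairs = 50L,
                                w_eps = 0.2, window_size = 100L,
                                top_k = 300L, nthread = 1L,
                                out_tsv = NULL) {
  rows <- list()
  for (w_ep in w_ep_grid) for (sd_ in seeds) {
    cfg <- simulation_config(n_samples = n_samples, n_snps = n_snps,
                             n_linear = n_linear,
                             n_epistatic_pairs = n_epistatic_pairs,
                             w_l = max(0, 1 - w_ep - w_eps), w_ep = w_ep,
                             w_eps = w_eps, seed = sd_)
    sim <- simulate_dataset(cfg)
    ds <- sim$dataset
    plan <- partition_windows(n_snps, window_size, "forward")
    sres <- run_window_selection(ds, plan,
                                 learner_params(nthread = nthread,
                                                seed = sd_),
                                 use_covariates = FALSE)
    top <- select_top_snps(sres, top_k)
    ep <- sim$truth$epistatic_pairs
    ep_snps <- c(ep$snp_a, ep$snp_b)
    frac_ep <- mean(ep_snps %in% top)
    frac_pairs <- mean(ep$snp_a %in% top & ep$snp_b %in% top)
    frac_lin <- if (nrow(sim$truth$linear_snps))
      mean(sim$truth$linear_snps$snp %in% top) else NA_real_
    splits <- lapply(c(train = "train", validation = "validation",
                       test = "test"), function(s) get_split(ds, s))
    xgb <- fit_model(splits$train, splits$validation,
                     model_spec(learner = "boosted", depth = 2L, seed = sd_),
                     snp_idx = top, use_covariates = FALSE,
                     nthread = nthread)
    las <- fit_model(splits$train, splits$validation,
                     model_spec(learner = "l1_linear", seed = sd_),
                     use_covariates = FALSE, nthread = nthread)
    rows[[length(rows) + 1L]] <- data.frame(
      w_ep = w_ep, seed = sd_,
      lasso_r2 = r_squared(splits$test$phenotype,
                           predict(las, splits$test)),
      xgb_r2 = r_squared(splits$test$phenotype, predict(xgb, splits$test)),
      frac_epistatic_snps = frac_ep, frac_epistatic_pairs = frac_pairs,
      frac_linear_snps = frac_lin)
  }
  res <- do.call(rbind, rows)
  if (!is.null(out_tsv)) {
    agg <- do.call(rbind, lapply(split(res, res$w_ep), function(d) {
      num <- d[, setdiff(names(d), c("w_ep", "seed"))]
      data.frame(w_ep = d$w_ep[1],
                 as.list(colMeans(num)),
                 stats::setNames(as.list(apply(num, 2, stats::sd)),
                                 paste0(names(num), "_sd")))
    }))
    utils::write.table(agg, out_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  res
}
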