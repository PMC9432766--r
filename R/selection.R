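#' Partition SNPs into selection windows
#'
#' Splits the SNP sequence into disjoint windows of `window_size` consecutive
#' SNPs (the last window may be shorter) and fixes the traversal order of the
#' selection chain: `forward` walks the genome in order, `backward` traverses
#' the same windows in reverse, and `shuffled` forms windows on a seeded
#' permutation of SNP indices.
#'
#' @param n_snps Number of SNPs.
#' @param window_size SNPs per window (default 10000, the scale used for
#'   biobank-size SNP panels; scale down freely for smaller panels).
#' @param order `"forward"`, `"backward"` or `"shuffled"`.
#' @param shuffle_seed Seed for the `"shuffled"` order.
#' @return An object of class `window_plan` with `windows`, a list of SNP
#'   index vectors in traversal order.
#' @export
partition_windows <- function(n_snps, window_size = 10000L,
                              order = c("forward", "backward", "shuffled"),
                              shuffle_seed = 1L) {
  order <- match.arg(order)
  if (n_snps < 1 || window_size < 1) stop_input("bad window parameters")
  idx <- seq_len(n_snps)
  if (order == "shuffled")
    idx <- with_seed(shuffle_seed, sample.int(n_snps))
  windows <- split(idx, (seq_len(n_snps) - 1L) %/% window_size)
  names(windows) <- NULL
  if (order == "backward") windows <- rev(windows)
  structure(list(window_size = as.integer(window_size), order = order,
                 shuffle_seed = as.integer(shuffle_seed), windows = windows),
            class = "window_plan")
}

#' @export
print.window_plan <- function(x, ...) {
  cat("window_plan:", length(x$windows), "windows of size", x$window_size,
      "| order:", x$order, "\n")
  invisible(x)
}

#' Boosted-learner parameters for selection and prediction
#'
#' @param depth Tree depth (1 = additive stumps, 2 = pairwise interactions).
#' @param eta Learning rate.
#' @param alpha L1 regularization on leaf weights (the headline models use
#'   values of 15-20).
#' @param max_trees Cap on boosting rounds per fit.
#' @param early_stopping_patience Rounds without validation improvement
#'   before stopping.
#' @param nthread Threads for the learner (1 keeps runs reproducible across
#'   machines; hist-based training is deterministic either way).
#' @param seed Seed passed to the learner.
#' @return A plain list of learner parameters.
#' @export
learner_params <- function(depth = 2L, eta = 0.1, alpha = 15,
                           max_trees = 2000L,
                           early_stopping_patience = 25L,
                           nthread = 1L, seed = 1L) {
  if (!depth %in% c(1L, 2L)) stop_input("depth must be 1 or 2")
  list(depth = as.integer(depth), eta = eta, alpha = alpha,
       max_trees = as.integer(max_trees),
       early_stopping_patience = as.integer(early_stopping_patience),
       nthread = as.integer(nthread), seed = as.integer(seed))
}

# Dense double feature matrix for a set of SNP columns (+ covariates);
# missing genotype calls stay NA and are routed natively by the learner.
feature_matrix <- function(dataset, snp_idx, use_covariates = TRUE) {
  x <- dataset$genotypes[, snp_idx, drop = FALSE]
  storage.mode(x) <- "double"
  if (use_covariates && !is.null(dataset$covariates))
    x <- cbind(x, dataset$covariates)
  x
}

xgb_objective <- function(kind) {
  if (kind == "binary")
    list(objective = "binary:logistic", eval_metric = "auc", maximize = TRUE)
  else
    list(objective = "reg:squarederror", eval_metric = "rmse",
         maximize = FALSE)
}

# Fit one boosted model with early stopping; returns booster, best
# iteration (0-based index of the last used round) and per-feature raw total
# gain restricted to the used trees.
fit_boosted_window <- function(x_tr, y_tr, x_va, y_va, params, kind,
                               margin_tr = NULL, margin_va = NULL,
                               interaction_constraints = NULL) {
  dtr <- xgboost::xgb.DMatrix(x_tr, label = y_tr, base_margin = margin_tr,
                              nthread = params$nthread)
  dva <- xgboost::xgb.DMatrix(x_va, label = y_va, base_margin = margin_va,
                              nthread = params$nthread)
  obj <- xgb_objective(kind)
  xp <- list(max_depth = params$depth, eta = params$eta,
             alpha = params$alpha, objective = obj$objective,
             eval_metric = obj$eval_metric, tree_method = "hist",
             nthread = params$nthread, seed = params$seed)
  if (!is.null(interaction_constraints))
    xp$interaction_constraints <- interaction_constraints
  bst <- xgboost::xgb.train(params = xp, data = dtr,
                            nrounds = params$max_trees,
                            evals = list(val = dva),
                            early_stopping_rounds =
                              params$early_stopping_patience,
                            maximize = obj$maximize, verbose = 0)
  best <- xgboost::xgb.attributes(bst)$best_iteration
  best <- if (is.null(best)) xgboost::xgb.get.num.boosted.rounds(bst) - 1L
          else as.integer(best)
  tt <- xgboost::xgb.model.dt.tree(model = bst)
  tt <- tt[tt$Tree <= best & tt$Feature != "Leaf", , drop = FALSE]
  gain <- if (nrow(tt)) tapply(tt$Gain, tt$Feature, sum) else numeric(0)
  list(booster = bst, best_iteration = best, gain = gain,
       dtrain = dtr, dval = dva)
}

# Raw-margin predictions of a fitted window model (includes any base margin
# carried by the supplied matrices).
margin_predict <- function(fit, x, margin = NULL, nthread = 1L) {
  d <- xgboost::xgb.DMatrix(x, base_margin = margin, nthread = nthread)
  as.numeric(stats::predict(fit$booster, d, outputmargin = TRUE))
}

#' Windowed warm-started boosted SNP selection
#'
#' The core selection algorithm: a boosted model is fitted per window of
#' SNPs, and every model after the first receives the previous model's
#' per-sample prediction as a fixed additive baseline (warm start), so its
#' trees fit only the residual signal. This suppresses re-selection of SNPs
#' correlated with signal already captured in earlier windows. Per-window
#' feature importances (raw total split gain over the trees retained by early
#' stopping) are aggregated into a genome-wide importance vector.
#'
#' The per-window tree count is chosen by early stopping on the validation
#' split; chained baselines are propagated for both train and validation
#' samples so early stopping stays consistent along the chain.
#'
#' @param dataset A split-labelled [genotype_dataset()] with a phenotype.
#' @param plan A [window_plan()] covering the dataset's SNPs, from
#'   [partition_windows()].
#' @param params Learner parameters from [learner_params()]; selection
#'   defaults to depth-2 trees.
#' @param use_covariates Include covariates as features in every window model
#'   (importances are then conditional on them).
#' @return An object of class `selection_result` with `importance` (named
#'   per-SNP raw gain, 0 for SNPs never split on), `window_of`, `order_used`,
#'   `chain_predictions` (per-window train/validation margin vectors),
#'   `validation_metric` per window, and `learner_params`.
#' @export
run_window_selection <- function(dataset, plan, params = learner_params(),
                                 use_covariates = TRUE) {
  if (is.null(dataset$split)) stop_input("dataset needs split labels")
  if (is.null(dataset$phenotype)) stop_input("dataset needs a phenotype")
  p <- ncol(dataset$genotypes)
  if (!setequal(unlist(plan$windows), seq_len(p)))
    stop_input("window plan does not cover the dataset's SNPs")
  tr <- which(dataset$split == "train")
  va <- which(dataset$split == "validation")
  if (!length(tr)) stop_input("empty train split")
  if (!length(va)) stop_input("empty validation split")
  y_tr <- dataset$phenotype[tr]; y_va <- dataset$phenotype[va]
  kind <- dataset$phenotype_kind

  importance <- stats::setNames(numeric(p), dataset$map$snp_id)
  window_of <- stats::setNames(rep(NA_integer_, p), dataset$map$snp_id)
  margin_tr <- NULL; margin_va <- NULL
  chain <- list(); val_metric <- numeric(length(plan$windows))

  for (w in seq_along(plan$windows)) {
    snps <- plan$windows[[w]]
    window_of[snps] <- w
    x_all <- feature_matrix(dataset, snps, use_covariates)
    x_tr <- x_all[tr, , drop = FALSE]; x_va <- x_all[va, , drop = FALSE]
    fit <- tryCatch(
      fit_boosted_window(x_tr, y_tr, x_va, y_va, params, kind,
                         margin_tr = margin_tr, margin_va = margin_va),
      error = function(e) stop_input("learner failed on window ", w, ": ",
                                     conditionMessage(e)))
    snp_names <- dataset$map$snp_id[snps]
    hit <- intersect(names(fit$gain), snp_names)
    importance[hit] <- importance[hit] + fit$gain[hit]
    margin_tr <- margin_predict(fit, x_tr, margin_tr, params$nthread)
    margin_va <- margin_predict(fit, x_va, margin_va, params$nthread)
    chain[[w]] <- list(train = margin_tr, validation = margin_va)
    val_metric[w] <- if (kind == "binary") auc(y_va, margin_va)
                     else r_squared(y_va, margin_va)
  }
  structure(list(importance = importance, window_of = window_of,
                 order_used = plan$order, chain_predictions = chain,
                 validation_metric = val_metric, learner_params = params,
                 map = dataset$map),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("selection_result:", length(x$importance), "SNPs,",
      max(x$window_of, na.rm = TRUE), "windows, order", x$order_used, "\n")
  cat("  nonzero importances:", sum(x$importance > 0),
      "| final chain validation metric:",
      round(utils::tail(x$validation_metric, 1), 4), "\n")
  invisible(x)
}

#' Select the top-k SNPs by importance
#'
#' @param result A `selection_result` (or any named importance vector).
#' @param k Number of SNPs to return (`1 <= k <= n_snps`).
#' @return Integer vector of SNP indices ordered by decreasing importance,
#'   ties broken by genome order. Zero-importance SNPs are admitted only when
#'   fewer than `k` SNPs have positive importance (with a warning).
#' @export
select_top_snps <- function(result, k) {
  imp <- if (inherits(result, "selection_result")) result$importance
         else result
  p <- length(imp)
  if (k < 1 || k > p) stop_input("k must be in [1, n_snps]")
  ord <- order(-imp, seq_len(p))
  if (sum(imp > 0) < k)
    warning("only ", sum(imp > 0), " SNPs have positive importance; ",
            "padding to k = ", k, " in genome order")
  ord[seq_len(k)]
}

#' GWAS-style single-SNP association selection
#'
#' The conventional baseline selector: each SNP is tested one at a time in an
#' additive association model adjusted for the dataset's covariates, fitted
#' on the training split only. Quantitative phenotypes use the t-test of the
#' SNP coefficient in a linear model (computed via residualization on the
#' covariates); binary phenotypes use the Rao score test of adding the SNP to
#' a covariate-only logistic null model. Missing genotypes are mean-imputed
#' per SNP; monomorphic SNPs get p-value 1 and are never selected before
#' polymorphic ones.
#'
#' @param dataset A split-labelled [genotype_dataset()] with a phenotype.
#' @param k Number of SNPs to return (0 gives an empty selection).
#' @param use_covariates Adjust for the dataset's covariates.
#' @return A list with `snps` (indices of the `k` smallest-p SNPs, ties by
#'   genome order) and `p_values` (named per-SNP vector).
#' @export
gwas_select <- function(dataset, k, use_covariates = TRUE) {
  if (is.null(dataset$split)) stop_input("dataset needs split labels")
  tr <- which(dataset$split == "train")
  if (!length(tr)) stop_input("empty train split")
  g <- dataset$genotypes[tr, , drop = FALSE]
  storage.mode(g) <- "double"
  g <- impute_by_means(g, train_impute_means(g))
  y <- dataset$phenotype[tr]
  n <- length(tr); p <- ncol(g)
  covs <- if (use_covariates && !is.null(dataset$covariates))
    dataset$covariates[tr, , drop = FALSE] else NULL
  x0 <- cbind(`(Intercept)` = rep(1, n), covs)
  mono <- apply(g, 2, function(col) stats::var(col) == 0)

  if (dataset$phenotype_kind == "quantitative") {
    q <- qr(x0)
    ry <- qr.resid(q, y)
    rg <- qr.resid(q, g)
    df <- n - ncol(x0) - 1L
    ss_g <- colSums(rg^2)
    bnum <- colSums(rg * ry)
    beta <- bnum / ss_g
    rss <- sum(ry^2) - beta * bnum
    se <- sqrt(pmax(rss / df, 0) / ss_g)
    tstat <- beta / se
    pv <- 2 * stats::pt(-abs(tstat), df)
  } else {
    null_fit <- stats::glm.fit(x0, y, family = stats::binomial())
    mu <- null_fit$fitted.values
    wv <- mu * (1 - mu)
    res <- y - mu
    xw <- x0 * wv
    xtwx_inv <- solve(crossprod(x0, xw))
    u <- colSums(g * res)
    gw <- crossprod(xw, g)             # t(x0) W g
    v <- colSums(g^2 * wv) - colSums(gw * (xtwx_inv %*% gw))
    chi <- u^2 / v
    pv <- stats::pchisq(chi, df = 1, lower.tail = FALSE)
  }
  pv[mono | !is.finite(pv)] <- 1
  names(pv) <- dataset$map$snp_id
  snps <- if (k > 0) order(pv, seq_len(p))[seq_len(k)] else integer(0)
  list(snps = snps, p_values = pv)
}

#' Write a selection result as TSV
#'
#' @param result A `selection_result`.
#' @param path Output path; columns `snp_id`, `chrom`, `pos`, `importance`,
#'   `window`, `rank`.
#' @export
write_selection_tsv <- function(result, path) {
  rk <- integer(length(result$importance))
  rk[order(-result$importance, seq_along(result$importance))] <-
    seq_along(result$importance)
  utils::write.table(
    data.frame(snp_id = result$map$snp_id, chrom = result$map$chrom,
               pos = result$map$pos, importance = result$importance,
               window = result$window_of, rank = rk),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
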