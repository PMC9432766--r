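#' Predictive model specification
#'
#' @param learner `"boosted"` (gradient boosted trees) or `"l1_linear"`
#'   (L1-regularized linear/logistic regression, the linear baseline).
#' @param depth Tree depth for the boosted learner, 1 or 2. Depth-1 models
#'   are additive (equivalent to a linear model on one-hot-encoded
#'   genotypes); depth-2 models capture pairwise interactions.
#' @param alpha L1 penalty for the boosted learner.
#' @param eta Boosted learning rate.
#' @param lambda_path Optional penalty grid for `l1_linear`; `NULL` lets the
#'   path be chosen automatically. The final penalty maximizes the validation
#'   metric.
#' @param interaction_mode `"free"` or `"restricted"`. Restricted mode
#'   forbids SNPs and covariates from appearing in the same tree, forcing the
#'   fit to decompose as g(SNPs) + h(covariates).
#' @param max_trees,early_stopping_patience Early-stopping knobs on the
#'   validation metric.
#' @param seed Learner seed.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(learner = c("boosted", "l1_linear"), depth = 2L,
                       alpha = 15, eta = 0.1, lambda_path = NULL,
                       interaction_mode = c("free", "restricted"),
                       max_trees = 2000L, early_stopping_patience = 25L,
                       seed = 1L) {
  learner <- match.arg(learner)
  interaction_mode <- match.arg(interaction_mode)
  if (!depth %in% c(1L, 2L)) stop_input("depth must be 1 or 2")
  structure(list(learner = learner, depth = as.integer(depth), alpha = alpha,
                 eta = eta, lambda_path = lambda_path,
                 interaction_mode = interaction_mode,
                 max_trees = as.integer(max_trees),
                 early_stopping_patience = as.integer(early_stopping_patience),
                 seed = as.integer(seed)),
            class = "model_spec")
}

# Feature matrix + group labels for a dataset restricted to snp_idx.
model_features <- function(dataset, snp_idx, use_covariates = TRUE) {
  x <- feature_matrix(dataset, snp_idx, use_covariates)
  groups <- c(rep("snp", length(snp_idx)),
              rep("covariate",
                  if (use_covariates && !is.null(dataset$covariates))
                    ncol(dataset$covariates) else 0L))
  list(x = x, groups = groups)
}

#' Fit a predictive model on train/validation datasets
#'
#' Boosted models are trained with early stopping on the validation metric
#' (r-squared for quantitative phenotypes via RMSE, AUC for binary); missing
#' genotypes are passed to the learner natively. The L1 linear baseline is a
#' lasso (gaussian) or L1-logistic (binomial) path with the penalty chosen to
#' maximize the validation metric; genotypes are mean-imputed with training
#' means. In `restricted` mode the boosted learner's interaction constraints
#' confine each tree to one feature group (SNPs or covariates).
#'
#' @param train,validation [genotype_dataset()]s sharing SNPs/covariates
#'   (e.g. from [get_split()]).
#' @param spec A [model_spec()].
#' @param snp_idx Optional SNP index vector restricting the feature set
#'   (e.g. from [select_top_snps()]); default all SNPs.
#' @param use_covariates Include covariates as features.
#' @param nthread Learner threads.
#' @return An object of class `predictive_model` with the fitted learner,
#'   `feature_list`, `feature_groups`, `best_iteration` (boosted) or
#'   `lambda` (l1_linear), and `validation_metric`.
#' @export
fit_model <- function(train, validation, spec = model_spec(),
                      snp_idx = NULL, use_covariates = TRUE, nthread = 1L) {
  if (is.null(train$phenotype) || is.null(validation$phenotype))
    stop_input("train and validation need phenotypes")
  kind <- train$phenotype_kind
  snp_idx <- snp_idx %||% seq_len(ncol(train$genotypes))
  ftr <- model_features(train, snp_idx, use_covariates)
  fva <- model_features(validation, snp_idx, use_covariates)
  if (!identical(colnames(ftr$x), colnames(fva$x)))
    stop_input("train and validation feature columns differ")
  if (!is.null(train$covariates) && any(!is.finite(train$covariates)))
    stop_input("non-finite values in covariates")
  y_tr <- train$phenotype; y_va <- validation$phenotype
  if (kind == "binary" && length(unique(y_tr)) < 2)
    stop_input("binary train split has a single class")
  metric_fun <- if (kind == "binary") auc else r_squared

  if (spec$learner == "boosted") {
    constraints <- NULL
    if (spec$interaction_mode == "restricted") {
      gi <- split(seq_along(ftr$groups) - 1L, ftr$groups)
      constraints <- unname(gi[lengths(gi) > 0])
    }
    lp <- learner_params(depth = spec$depth, eta = spec$eta,
                         alpha = spec$alpha, max_trees = spec$max_trees,
                         early_stopping_patience =
                           spec$early_stopping_patience,
                         nthread = nthread, seed = spec$seed)
    fit <- fit_boosted_window(ftr$x, y_tr, fva$x, y_va, lp, kind,
                              interaction_constraints = constraints)
    score_va <- as.numeric(stats::predict(fit$booster, fva$x))
    model <- list(spec = spec, kind = kind, feature_list = colnames(ftr$x),
                  feature_groups = ftr$groups, snp_idx = snp_idx,
                  booster = fit$booster, best_iteration = fit$best_iteration,
                  validation_metric = metric_fun(y_va, score_va))
  } else {
    mu <- train_impute_means(ftr$x)
    x_tr <- impute_by_means(ftr$x, mu)
    x_va <- impute_by_means(fva$x, mu)
    fam <- if (kind == "binary") "binomial" else "gaussian"
    gfit <- glmnet::glmnet(x_tr, y_tr, family = fam,
                           lambda = spec$lambda_path)
    pv <- stats::predict(gfit, x_va,
                         type = if (kind == "binary") "response" else "link")
    met <- apply(pv, 2, function(s) metric_fun(y_va, s))
    best <- which.max(met)
    model <- list(spec = spec, kind = kind, feature_list = colnames(ftr$x),
                  feature_groups = ftr$groups, snp_idx = snp_idx,
                  glmnet_fit = gfit, impute_means = mu,
                  lambda = gfit$lambda[best],
                  validation_metric = unname(met[best]))
  }
  structure(model, class = "predictive_model")
}

#' @export
print.predictive_model <- function(x, ...) {
  cat("predictive_model:", x$spec$learner,
      if (x$spec$learner == "boosted") paste0("(depth ", x$spec$depth,
        if (x$spec$interaction_mode == "restricted") ", restricted" else "",
        ")") else "",
      "|", length(x$feature_list), "features |",
      if (x$kind == "binary") "AUC" else "r2", "=",
      round(x$validation_metric, 4), "\n")
  invisible(x)
}

# Resolve newdata (genotype_dataset or named matrix) to the model's feature
# order; errors on missing columns.
resolve_features <- function(model, newdata) {
  x <- if (inherits(newdata, "genotype_dataset"))
    feature_matrix(newdata,
                   match(model$feature_list[model$feature_groups == "snp"],
                         newdata$map$snp_id),
                   use_covariates = any(model$feature_groups == "covariate"))
  else as.matrix(newdata)
  if (is.null(colnames(x))) {
    if (ncol(x) != length(model$feature_list))
      stop_input("unnamed feature matrix of wrong width")
    colnames(x) <- model$feature_list
  }
  miss <- setdiff(model$feature_list, colnames(x))
  if (length(miss))
    stop_input("missing feature columns: ", paste(utils::head(miss, 5),
                                                  collapse = ", "))
  x[, model$feature_list, drop = FALSE]
}

#' Predict from a fitted model
#'
#' @param object A `predictive_model`.
#' @param newdata A [genotype_dataset()] or a numeric matrix with named
#'   columns covering the model's feature list (column order is irrelevant).
#' @param raw If `TRUE`, return raw margin scores (log-odds for binary
#'   models) instead of probabilities.
#' @param ... Unused.
#' @return Numeric per-sample score vector: raw prediction for quantitative
#'   phenotypes, probability for binary ones.
#' @export
predict.predictive_model <- function(object, newdata, raw = FALSE, ...) {
  x <- resolve_features(object, newdata)
  if (object$spec$learner == "boosted") {
    as.numeric(stats::predict(object$booster, x, outputmargin = raw))
  } else {
    x <- impute_by_means(x, object$impute_means)
    eta <- if (!is.null(object$glmnet_fit))
      as.numeric(stats::predict(object$glmnet_fit, x, s = object$lambda,
                                type = "link"))
    else
      as.numeric(x %*% object$coefficients) + object$intercept
    if (object$kind == "binary" && !raw) stats::plogis(eta) else eta
  }
}

#' Serialize a fitted model to disk
#'
#' Boosted models are written with the learner's native serializer
#' (`<prefix>.model.ubj`); L1 linear models store their intercept and
#' coefficients directly. Both get a JSON sidecar (`<prefix>.json`) with the
#' spec, feature list, groups, best iteration / penalty and validation
#' metric, so a model directory is self-describing.
#'
#' @param model A `predictive_model`.
#' @param prefix Output path prefix.
#' @return `prefix`, invisibly.
#' @export
save_model <- function(model, prefix) {
  side <- list(spec = unclass(model$spec), kind = model$kind,
               feature_list = model$feature_list,
               feature_groups = model$feature_groups,
               snp_idx = model$snp_idx,
               validation_metric = model$validation_metric)
  if (model$spec$learner == "boosted") {
    xgboost::xgb.save(model$booster, paste0(prefix, ".model.ubj"))
    side$best_iteration <- model$best_iteration
  } else {
    beta <- as.numeric(stats::coef(model$glmnet_fit, s = model$lambda))
    side$intercept <- beta[1]
    side$coefficients <- beta[-1]
    side$impute_means <- as.numeric(model$impute_means)
    side$lambda <- model$lambda
  }
  jsonlite::write_json(side, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(prefix)
}

#' Load a model serialized by [save_model()]
#'
#' @param prefix Path prefix used at save time.
#' @return A `predictive_model`. Reloaded L1 linear models predict from the
#'   stored coefficient vector.
#' @export
load_model <- function(prefix) {
  side <- jsonlite::read_json(paste0(prefix, ".json"),
                              simplifyVector = TRUE)
  spec <- do.call(model_spec, side$spec[setdiff(names(side$spec),
                                                c("lambda_path"))])
  model <- list(spec = spec, kind = side$kind,
                feature_list = side$feature_list,
                feature_groups = side$feature_groups,
                snp_idx = side$snp_idx,
                validation_metric = side$validation_metric)
  if (spec$learner == "boosted") {
    model$booster <- xgboost::xgb.load(paste0(prefix, ".model.ubj"))
    model$best_iteration <- side$best_iteration
  } else {
    model$intercept <- side$intercept
    model$coefficients <- side$coefficients
    model$impute_means <- stats::setNames(side$impute_means,
                                          side$feature_list)
    model$lambda <- side$lambda
  }
  structure(model, class = "predictive_model")
}

# Double-precision evaluation of a boosted model's margin from its dumped
# trees. The learner predicts in single precision, whose ~1e-7 rounding noise
# would mask exact structural identities (additivity, group decomposition);
# summing per-tree leaf values in double keeps those residuals at true zero.
# The constant base score is omitted: the probes only use differences.
boosted_margin_exact <- function(model, x) {
  dt <- xgboost::xgb.model.dt.tree(model = model$booster)
  dt <- dt[dt$Tree <= model$best_iteration, , drop = FALSE]
  node_key <- paste(dt$Tree, dt$ID)
  is_leaf <- dt$Feature == "Leaf"
  feat_idx <- match(dt$Feature, model$feature_list)
  yes_row <- match(paste(dt$Tree, dt$Yes), node_key)
  no_row <- match(paste(dt$Tree, dt$No), node_key)
  miss_row <- match(paste(dt$Tree, dt$Missing), node_key)
  roots <- which(dt$Node == 0)
  out <- numeric(nrow(x))
  for (i in seq_len(nrow(x))) {
    acc <- 0
    for (r in roots) {
      while (!is_leaf[r]) {
        v <- x[i, feat_idx[r]]
        r <- if (is.na(v)) miss_row[r]
             else if (v < dt$Split[r]) yes_row[r] else no_row[r]
      }
      acc <- acc + dt$Gain[r]   # leaf value is reported in the Gain column
    }
    out[i] <- acc
  }
  out
}

probe_margin_fun <- function(model) {
  if (model$spec$learner == "boosted")
    function(m) boosted_margin_exact(model, m)
  else
    function(m) predict(model, m, raw = TRUE)
}

# Default probe matrix: sample rows of the training features.
default_probe <- function(model, probe_data, n_rows = 20L) {
  x <- resolve_features(model, probe_data)
  if (nrow(x) > n_rows)
    x <- x[seq(1L, nrow(x), length.out = n_rows), , drop = FALSE]
  x
}

#' Measure departure from additivity
#'
#' For probe pairs `(x, x')` differing in exactly one feature, an additive
#' model's prediction difference `f(x) - f(x')` depends only on that
#' feature's two values. This probe sweeps each feature over a set of values
#' (genotypes 0/1/2 for SNPs; observed quantile values for covariates) on a
#' set of background rows and returns the maximum absolute deviation of the
#' difference from its background-mean. Depth-1 boosted models and linear
#' models return 0 up to floating-point error; interaction-bearing models
#' return a positive residual.
#'
#' @param model A fitted `predictive_model`.
#' @param probe_data A [genotype_dataset()] or feature matrix supplying
#'   background rows.
#' @param n_rows Number of background rows probed.
#' @return Maximum absolute interaction residual (scalar).
#' @export
verify_additivity <- function(model, probe_data, n_rows = 20L) {
  x <- default_probe(model, probe_data, n_rows)
  f <- probe_margin_fun(model)
  res <- 0
  for (k in seq_along(model$feature_list)) {
    vals <- if (model$feature_groups[k] == "snp") c(0, 1, 2)
            else unique(stats::quantile(x[, k], c(0.1, 0.5, 0.9), na.rm = TRUE))
    if (length(vals) < 2) next
    base <- x; base[, k] <- vals[1]
    f0 <- f(base)
    for (v in vals[-1]) {
      alt <- x; alt[, k] <- v
      d <- f(alt) - f0
      res <- max(res, max(abs(d - mean(d))))
    }
  }
  res
}

#' Measure departure from a SNP + covariate decomposition
#'
#' A model of the form `g(SNPs) + h(covariates)` has
#' `f(s, c) - f(s, c')` independent of the SNP block. This probe evaluates
#' that difference over a grid of SNP-block rows and covariate-block pairs
#' and returns the maximum absolute deviation from the SNP-block mean.
#' Models fitted with `interaction_mode = "restricted"` return 0 up to
#' floating point; free models fitted on data with genuine SNP-covariate
#' interactions return a positive residual (the diagnostic is applicable to
#' both modes).
#'
#' @param model A fitted `predictive_model` with covariate features.
#' @param probe_data Background rows as in [verify_additivity()].
#' @param n_rows Number of SNP-block background rows.
#' @return Maximum absolute cross-group residual (scalar).
#' @export
verify_group_decomposition <- function(model, probe_data, n_rows = 20L) {
  if (!any(model$feature_groups == "covariate"))
    stop_input("model has no covariate features")
  x <- default_probe(model, probe_data, n_rows)
  cov_cols <- which(model$feature_groups == "covariate")
  f <- probe_margin_fun(model)
  # covariate configurations: a few observed rows
  cfg_rows <- unique(round(seq(1L, nrow(x), length.out = 4L)))
  res <- 0
  for (i in cfg_rows[-1]) {
    a <- x; b <- x
    a[, cov_cols] <- rep(x[cfg_rows[1], cov_cols], each = nrow(x))
    b[, cov_cols] <- rep(x[i, cov_cols], each = nrow(x))
    d <- f(b) - f(a)   # varies over SNP-block rows
    res <- max(res, max(abs(d - mean(d))))
  }
  res
}
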