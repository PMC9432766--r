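#' Coefficient of determination
#'
#' `1 - SS_res / SS_tot`, with the total sum of squares taken about the
#' target mean. Can be negative for predictions worse than the mean.
#'
#' @param targets,predictions Equal-length numeric vectors (length >= 2).
#' @export
r_squared <- function(targets, predictions) {
  if (length(targets) != length(predictions) || length(targets) < 2)
    stop_input("need equal-length vectors of length >= 2")
  sst <- sum((targets - mean(targets))^2)
  if (sst == 0) stop_input("constant targets: r2 undefined")
  1 - sum((targets - predictions)^2) / sst
}

#' ROC AUC (Mann-Whitney form)
#'
#' Probability that a random positive outscores a random negative, with
#' tied scores counted 1/2.
#'
#' @param targets 0/1 vector with both classes present.
#' @param scores Numeric score vector.
#' @export
auc <- function(targets, scores) {
  if (length(targets) != length(scores))
    stop_input("length mismatch")
  n1 <- sum(targets == 1); n0 <- sum(targets == 0)
  if (n1 == 0 || n0 == 0) stop_input("AUC undefined with a single class")
  r <- rank(scores)
  (sum(r[targets == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Subsampling standard error of a metric
#'
#' Computes the metric on `n_repeats` random subsamples of size `M` drawn
#' without replacement and rescales their standard deviation to the
#' full-sample scale by `sqrt(M / n) / sqrt(1 - M / n)`. The
#' `sqrt(1 - M / n)` divisor is the finite-population correction: subsamples
#' drawn without replacement from one fixed sample fluctuate around the
#' full-sample statistic with variance `(1 - M/n) * sigma^2_M`, so omitting
#' it would systematically understate the standard error (by `sqrt(2)` at
#' the default `M = n/2`). For AUC, single-class subsamples are rejected and
#' redrawn (error after 1000 rejections).
#'
#' @param targets,predictions Full-sample vectors.
#' @param metric `"r2"` or `"auc"`.
#' @param M Subsample size (default `n / 2`).
#' @param n_repeats Number of subsamples (default 200).
#' @param seed Seed making the estimate reproducible.
#' @return Standard error estimate (scalar).
#' @export
se_subsampling <- function(targets, predictions, metric = c("r2", "auc"),
                           M = floor(length(targets) / 2), n_repeats = 200L,
                           seed = 1L) {
  metric <- match.arg(metric)
  mf <- metric_function(metric)
  n <- length(targets)
  if (M >= n || M < 2) stop_input("M must be in [2, n)")
  if (n_repeats < 2) stop_input("n_repeats must be >= 2")
  vals <- with_seed(seed, {
    vapply(seq_len(n_repeats), function(i) {
      rejections <- 0L
      repeat {
        idx <- sample.int(n, M)
        if (metric != "auc" || length(unique(targets[idx])) > 1) break
        rejections <- rejections + 1L
        if (rejections >= 1000L)
          stop_input("subsample repeatedly single-class; increase M")
      }
      mf(targets[idx], predictions[idx])
    }, numeric(1))
  })
  stats::sd(vals) * sqrt(M / n) / sqrt(1 - M / n)
}

#' Closed-form AUC standard error (Hanley-McNeil)
#'
#' `SE^2 = (A(1-A) + (n1-1)(Q1 - A^2) + (n0-1)(Q2 - A^2)) / (n1 n0)` with
#' `Q1 = A / (2 - A)` and `Q2 = 2 A^2 / (1 + A)`, where `A` is the observed
#' AUC and `n1`, `n0` the class counts.
#'
#' @param targets 0/1 vector with both classes present.
#' @param scores Numeric score vector.
#' @export
se_auc_analytic <- function(targets, scores) {
  a <- auc(targets, scores)
  n1 <- sum(targets == 1); n0 <- sum(targets == 0)
  q1 <- a / (2 - a)
  q2 <- 2 * a^2 / (1 + a)
  sqrt((a * (1 - a) + (n1 - 1) * (q1 - a^2) + (n0 - 1) * (q2 - a^2)) /
         (n1 * n0))
}

#' Mean pairwise genotype r-squared of a SNP subset
#'
#' Mean of squared Pearson correlations over all unordered distinct pairs of
#' the subset's genotype columns (missing calls handled pairwise-complete),
#' the linkage-disequilibrium diagnostic used to compare selection methods.
#' Pairs involving a monomorphic SNP contribute 0 with a warning.
#'
#' @param genotypes A [genotype_dataset()] or genotype matrix.
#' @param snp_subset Column indices (or SNP ids) of the subset, length >= 2.
#' @export
mean_pairwise_r2 <- function(genotypes, snp_subset) {
  g <- if (inherits(genotypes, "genotype_dataset")) genotypes$genotypes
       else genotypes
  if (is.character(snp_subset) && inherits(genotypes, "genotype_dataset"))
    snp_subset <- match(snp_subset, genotypes$map$snp_id)
  if (length(snp_subset) < 2) stop_input("need at least 2 SNPs")
  x <- g[, snp_subset, drop = FALSE]
  storage.mode(x) <- "double"
  cm <- suppressWarnings(stats::cor(x, use = "pairwise.complete.obs"))
  if (anyNA(cm[upper.tri(cm)])) {
    warning("monomorphic SNP(s) in subset; their pairs contribute r2 = 0")
    cm[is.na(cm)] <- 0
  }
  mean(cm[upper.tri(cm)]^2)
}

#' Metric report with standard errors
#'
#' @param targets,predictions Evaluation vectors.
#' @param metric `"r2"` or `"auc"`.
#' @param M,n_repeats,seed Passed to [se_subsampling()].
#' @return A list of class `metric_report`: `metric_name`, `value`,
#'   `se_subsampling`, `se_analytic` (AUC only), `n_samples`,
#'   `subsample_size`, `n_repeats`, `seed`.
#' @export
metric_report <- function(targets, predictions, metric = c("r2", "auc"),
                          M = floor(length(targets) / 2), n_repeats = 200L,
                          seed = 1L) {
  metric <- match.arg(metric)
  mf <- metric_function(metric)
  structure(list(metric_name = metric,
                 value = mf(targets, predictions),
                 se_subsampling = se_subsampling(targets, predictions, metric,
                                                 M, n_repeats, seed),
                 se_analytic = if (metric == "auc")
                   se_auc_analytic(targets, predictions),
                 n_samples = length(targets), subsample_size = M,
                 n_repeats = n_repeats, seed = seed),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("%s = %.4f (subsampling SE %.4f%s, n = %d)\n", x$metric_name,
              x$value, x$se_subsampling,
              if (!is.null(x$se_analytic))
                sprintf(", analytic SE %.4f", x$se_analytic) else "",
              x$n_samples))
  invisible(x)
}
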