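#' Genotype/phenotype dataset container
#'
#' Bundles a biallelic genotype matrix coded by alternate-allele count
#' (0 = homozygous reference, 1 = heterozygote, 2 = homozygous alternative,
#' `NA` = missing call) together with variant metadata, an optional phenotype,
#' optional covariates and optional train/validation/test split labels.
#'
#' @param genotypes Integer matrix, samples in rows, SNPs in columns; entries
#'   in `{0, 1, 2, NA}`.
#' @param map Data frame of variant metadata with columns `snp_id`, `chrom`,
#'   `pos` (and optionally `a1`, `a2`). One row per genotype column, in column
#'   order. Variant identifiers must be unique and the order must be
#'   consistent with `(chrom, pos)`.
#' @param sample_ids Character vector of sample identifiers.
#' @param phenotype Optional numeric vector (quantitative) or 0/1 vector
#'   (binary), one value per sample.
#' @param phenotype_kind `"quantitative"` or `"binary"`.
#' @param covariates Optional numeric matrix with named columns, one row per
#'   sample.
#' @param split Optional character/factor vector with values in
#'   `c("train", "validation", "test")`, one per sample.
#'
#' @return An object of class `genotype_dataset`.
#' @export
genotype_dataset <- function(genotypes, map, sample_ids,
                             phenotype = NULL,
                             phenotype_kind = c("quantitative", "binary"),
                             covariates = NULL, split = NULL) {
  phenotype_kind <- match.arg(phenotype_kind)
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  n <- nrow(genotypes); p <- ncol(genotypes)
  if (!is.data.frame(map) || !all(c("snp_id", "chrom", "pos") %in% names(map)))
    stop_input("map must be a data.frame with columns snp_id, chrom, pos")
  if (nrow(map) != p)
    stop_input("map has ", nrow(map), " rows but genotypes has ", p, " columns")
  if (anyDuplicated(map$snp_id))
    stop_input("snp_ids must be unique")
  if (length(sample_ids) != n)
    stop_input("sample_ids length does not match genotype rows")
  ci <- chrom_index(map$chrom)
  if (p > 1) {
    dc <- diff(ci); dp <- diff(map$pos)
    if (any(dc < 0 | (dc == 0 & dp < 0)))
      stop_input("SNPs must be ordered by (chromosome, position)")
  }
  bad <- genotypes[!is.na(genotypes)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L))
    stop_input("genotype entries must be in {0, 1, 2, NA}")
  if (!is.null(phenotype)) {
    if (length(phenotype) != n) stop_input("phenotype length mismatch")
    if (phenotype_kind == "binary" &&
        !all(phenotype[!is.na(phenotype)] %in% c(0, 1)))
      stop_input("binary phenotype must contain only 0/1")
  }
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != n) stop_input("covariates row mismatch")
    if (is.null(colnames(covariates)))
      colnames(covariates) <- paste0("COV", seq_len(ncol(covariates)))
  }
  if (!is.null(split)) {
    split <- as.character(split)
    if (length(split) != n) stop_input("split length mismatch")
    if (!all(split %in% c("train", "validation", "test")))
      stop_input("split labels must be train/validation/test")
  }
  rownames(genotypes) <- as.character(sample_ids)
  colnames(genotypes) <- map$snp_id
  structure(list(genotypes = genotypes, map = map,
                 sample_ids = as.character(sample_ids),
                 phenotype = phenotype, phenotype_kind = phenotype_kind,
                 covariates = covariates, split = split),
            class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat("genotype_dataset:", nrow(x$genotypes), "samples x",
      ncol(x$genotypes), "SNPs\n")
  cat("  phenotype:", if (is.null(x$phenotype)) "none" else x$phenotype_kind,
      "| covariates:",
      if (is.null(x$covariates)) 0 else ncol(x$covariates), "\n")
  if (!is.null(x$split)) {
    tb <- table(factor(x$split, c("train", "validation", "test")))
    cat("  split:", paste(names(tb), tb, sep = "=", collapse = " "), "\n")
  }
  invisible(x)
}

#' @export
dim.genotype_dataset <- function(x) dim(x$genotypes)

#' Subset a dataset by samples and/or SNPs
#'
#' @param dataset A [genotype_dataset()].
#' @param samples,snps Index vectors (integer, logical, or id character).
#' @return A `genotype_dataset` restricted to the requested rows/columns.
#' @export
subset_dataset <- function(dataset, samples = NULL, snps = NULL) {
  si <- seq_along(dataset$sample_ids)
  vi <- seq_len(ncol(dataset$genotypes))
  if (!is.null(samples)) {
    si <- if (is.character(samples)) match(samples, dataset$sample_ids)
          else si[samples]
    if (anyNA(si)) stop_input("unknown sample ids in subset")
  }
  if (!is.null(snps)) {
    vi <- if (is.character(snps)) match(snps, dataset$map$snp_id) else vi[snps]
    if (anyNA(vi)) stop_input("unknown snp ids in subset")
  }
  genotype_dataset(dataset$genotypes[si, vi, drop = FALSE],
                   dataset$map[vi, , drop = FALSE],
                   dataset$sample_ids[si],
                   phenotype = dataset$phenotype[si],
                   phenotype_kind = dataset$phenotype_kind,
                   covariates = if (!is.null(dataset$covariates))
                     dataset$covariates[si, , drop = FALSE],
                   split = dataset$split[si])
}

#' Extract one split of a dataset
#'
#' @param dataset A split-labelled [genotype_dataset()].
#' @param which One of `"train"`, `"validation"`, `"test"`.
#' @export
get_split <- function(dataset, which = c("train", "validation", "test")) {
  which <- match.arg(which)
  if (is.null(dataset$split)) stop_input("dataset has no split labels")
  subset_dataset(dataset, samples = dataset$split == which)
}

#' Train/validation/test split specification
#'
#' @param train_fraction,validation_fraction,test_fraction Positive
#'   proportions summing to 1 (tolerance 1e-9).
#' @param seed Integer seed making the split deterministic.
#' @return An object of class `split_spec`.
#' @export
split_spec <- function(train_fraction = 0.8, validation_fraction = 0.1,
                       test_fraction = 0.1, seed = 1L) {
  f <- c(train_fraction, validation_fraction, test_fraction)
  if (any(f <= 0)) stop_input("split fractions must be positive")
  if (abs(sum(f) - 1) > 1e-9) stop_input("split fractions must sum to 1")
  structure(list(train_fraction = train_fraction,
                 validation_fraction = validation_fraction,
                 test_fraction = test_fraction, seed = as.integer(seed)),
            class = "split_spec")
}

#' Assign train/validation/test labels
#'
#' Samples are assigned to splits uniformly at random (optionally stratified
#' by case status for binary phenotypes); split sizes are the rounded
#' fractions of the sample count. Deterministic given `spec$seed`.
#'
#' @param dataset A [genotype_dataset()].
#' @param spec A [split_spec()].
#' @param stratify If `TRUE` and the phenotype is binary, cases and controls
#'   are split separately so prevalence is balanced across splits.
#' @return The dataset with `$split` filled in.
#' @export
make_splits <- function(dataset, spec = split_spec(), stratify = FALSE) {
  n <- nrow(dataset$genotypes)
  sizes <- c(round(spec$train_fraction * n),
             round(spec$validation_fraction * n))
  sizes <- c(sizes, n - sum(sizes))
  if (n >= 3 && any(sizes < 1))
    stop_input("split fractions give an empty split for n = ", n)
  split <- character(n)
  if (stratify && dataset$phenotype_kind == "binary" &&
      !is.null(dataset$phenotype)) {
    for (cls in c(0, 1)) {
      idx <- which(dataset$phenotype == cls)
      m <- length(idx)
      sz <- c(round(spec$train_fraction * m), round(spec$validation_fraction * m))
      sz <- c(sz, m - sum(sz))
      perm <- with_seed(spec$seed + cls, sample.int(m))
      split[idx[perm]] <- rep(c("train", "validation", "test"),
                              pmax(sz, 0L))[seq_len(m)]
    }
  } else {
    perm <- with_seed(spec$seed, sample.int(n))
    split[perm] <- rep(c("train", "validation", "test"),
                       pmax(sizes, 0L))[seq_len(n)]
  }
  dataset$split <- split
  dataset
}

#' Minor allele frequencies
#'
#' @param dataset A [genotype_dataset()].
#' @return Numeric vector of per-SNP minor allele frequencies computed over
#'   non-missing calls (`NaN` for all-missing columns).
#' @export
compute_maf <- function(dataset) {
  p <- colMeans(dataset$genotypes, na.rm = TRUE) / 2
  pmin(p, 1 - p)
}

#' Filter SNPs by minor allele frequency
#'
#' Retains SNPs with MAF greater than or equal to `min_maf` (computed over
#' non-missing calls); SNP order is preserved. The inclusive boundary follows
#' the common convention for frequency cutoffs.
#'
#' @param dataset A [genotype_dataset()].
#' @param min_maf Cutoff in `[0, 0.5]`; the headline preprocessing uses 0.005.
#' @export
filter_maf <- function(dataset, min_maf = 0.005) {
  if (min_maf < 0 || min_maf > 0.5) stop_input("min_maf must be in [0, 0.5]")
  maf <- compute_maf(dataset)
  keep <- !is.na(maf) & maf >= min_maf
  if (!any(keep)) warning("no SNPs pass the MAF filter; returning empty dataset")
  subset_dataset(dataset, snps = keep)
}

#' Train-only principal components of the genotype matrix
#'
#' Fits a PCA on the training split exclusively (genotypes mean-imputed per
#' SNP using training means, centred and scaled by training statistics;
#' zero-variance SNPs are dropped from the decomposition). Scores for
#' validation and test samples are projections onto the training loadings, so
#' the held-out splits never influence the components.
#'
#' @param dataset A split-labelled [genotype_dataset()].
#' @param k Number of components (`1 <= k <= min(n_train - 1, n_snps)`).
#' @return A list of class `train_pca` with elements `scores` (all samples,
#'   columns `PC1..PCk`), `loadings`, `center`, `scale`, `snp_idx`.
#' @export
compute_train_pcs <- function(dataset, k = 10L) {
  if (is.null(dataset$split)) stop_input("dataset must be split first")
  tr <- dataset$split == "train"
  g <- dataset$genotypes
  storage.mode(g) <- "double"
  mu <- train_impute_means(g[tr, , drop = FALSE])
  g <- impute_by_means(g, mu)
  ctr <- colMeans(g[tr, , drop = FALSE])
  sdv <- apply(g[tr, , drop = FALSE], 2, stats::sd)
  use <- sdv > 0
  if (k < 1 || k > min(sum(tr) - 1L, sum(use)))
    stop_input("k = ", k, " exceeds the rank available from the train split")
  x <- sweep(sweep(g[, use, drop = FALSE], 2, ctr[use]), 2, sdv[use], "/")
  pc <- stats::prcomp(x[tr, , drop = FALSE], center = FALSE, scale. = FALSE,
                      rank. = k)
  scores <- x %*% pc$rotation[, seq_len(k), drop = FALSE]
  colnames(scores) <- paste0("PC", seq_len(k))
  rownames(scores) <- dataset$sample_ids
  structure(list(scores = scores,
                 loadings = pc$rotation[, seq_len(k), drop = FALSE],
                 center = ctr[use], scale = sdv[use], snp_idx = which(use)),
            class = "train_pca")
}

#' Append train-only PC scores as covariates
#'
#' @param dataset A split-labelled [genotype_dataset()].
#' @param k Number of components to append (named `PC1..PCk`).
#' @return The dataset with PC score columns appended to `$covariates`.
#' @export
add_pc_covariates <- function(dataset, k = 10L) {
  pcs <- compute_train_pcs(dataset, k)
  dataset$covariates <- cbind(dataset$covariates, pcs$scores)
  dataset
}
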