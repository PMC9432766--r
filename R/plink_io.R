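# PLINK 1 binary I/O.
#
# bed layout: 3 magic bytes 0x6c 0x1b 0x01 (SNP-major), then ceil(n/4) bytes
# per variant, 2 bits per sample, low bits first within each byte:
#   00 homozygous A1, 01 missing, 10 heterozygote, 11 homozygous A2.
# A1 is taken as the alternate allele, so the stored dosage (count of A1)
# matches the 0/1/2 alternate-allele coding of genotype_dataset.

plink_magic <- as.raw(c(0x6c, 0x1b, 0x01))

# 256 x 4 lookup: byte value -> four genotype codes (NA = missing).
bed_decode_lut <- local({
  two_bit <- c(2L, NA_integer_, 1L, 0L)  # codes 00, 01, 10, 11
  lut <- matrix(NA_integer_, 256, 4)
  for (b in 0:255)
    for (s in 0:3)
      lut[b + 1L, s + 1L] <- two_bit[bitwAnd(bitwShiftR(b, 2L * s), 3L) + 1L]
  lut
})

encode_bed_column <- function(g, n_bytes) {
  # inverse of bed_decode_lut: genotype 2 -> 00, NA -> 01, 1 -> 10, 0 -> 11
  code <- ifelse(is.na(g), 1L, c(3L, 2L, 0L)[g + 1L])
  code <- c(code, rep(0L, 4L * n_bytes - length(code)))
  m <- matrix(code, nrow = 4)
  as.raw(m[1, ] + bitwShiftL(m[2, ], 2) + bitwShiftL(m[3, ], 4) +
         bitwShiftL(m[4, ], 6))
}

#' Write a dataset as PLINK 1 bed/bim/fam plus a phenotype table
#'
#' @param dataset A [genotype_dataset()].
#' @param prefix Output path prefix; writes `prefix.bed`, `prefix.bim`,
#'   `prefix.fam` and, when a phenotype is present, `prefix.pheno.tsv`
#'   (columns `sample_id`, `phenotype`, then covariates).
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(dataset, prefix) {
  g <- dataset$genotypes
  n <- nrow(g); p <- ncol(g)
  n_bytes <- ceiling(n / 4)
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(plink_magic, con)
  for (j in seq_len(p))
    writeBin(encode_bed_column(g[, j], n_bytes), con)
  map <- dataset$map
  bim <- data.frame(chrom = map$chrom, snp_id = map$snp_id, cm = 0,
                    pos = map$pos,
                    a1 = map$a1 %||% rep("A", p), a2 = map$a2 %||% rep("B", p))
  utils::write.table(bim, paste0(prefix, ".bim"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  fam <- data.frame(fid = dataset$sample_ids, iid = dataset$sample_ids,
                    pat = 0, mat = 0, sex = 0, pheno = -9)
  utils::write.table(fam, paste0(prefix, ".fam"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  if (!is.null(dataset$phenotype)) {
    tab <- data.frame(sample_id = dataset$sample_ids,
                      phenotype = dataset$phenotype)
    if (!is.null(dataset$covariates))
      tab <- cbind(tab, as.data.frame(dataset$covariates))
    utils::write.table(tab, paste0(prefix, ".pheno.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(prefix)
}

read_bim <- function(bim_path) {
  bim <- utils::read.table(bim_path, header = FALSE, sep = "",
                           stringsAsFactors = FALSE,
                           col.names = c("chrom", "snp_id", "cm", "pos",
                                         "a1", "a2"),
                           colClasses = c("character", "character", "numeric",
                                          "integer", "character", "character"))
  bim
}

#' Load PLINK 1 binary genotypes with a phenotype table
#'
#' Reads a bed/bim/fam triplet and joins it with a tab- or comma-separated
#' phenotype table keyed by sample id. The returned dataset is restricted to
#' the samples present in both the fam file and the table (fam order);
#' variant order follows the bim file; missing genotype calls are kept as
#' `NA`.
#'
#' @param bed_path,bim_path,fam_path Paths to the PLINK files. `bim_path` and
#'   `fam_path` default to `bed_path` with the extension swapped.
#' @param phenotype_table_path Optional path to a TSV/CSV with a header, a
#'   `sample_id` column, a `phenotype` column and any number of covariate
#'   columns.
#' @param phenotype_kind `"quantitative"` or `"binary"`.
#' @return A [genotype_dataset()].
#' @export
load_plink <- function(bed_path, bim_path = sub("\\.bed$", ".bim", bed_path),
                       fam_path = sub("\\.bed$", ".fam", bed_path),
                       phenotype_table_path = NULL,
                       phenotype_kind = c("quantitative", "binary")) {
  phenotype_kind <- match.arg(phenotype_kind)
  for (f in c(bed_path, bim_path, fam_path))
    if (!file.exists(f)) stop_input("file not found: ", f)
  bim <- read_bim(bim_path)
  fam <- utils::read.table(fam_path, header = FALSE, sep = "",
                           stringsAsFactors = FALSE)
  sample_ids <- as.character(fam[[2]])
  n <- length(sample_ids); p <- nrow(bim)
  raw <- readBin(bed_path, "raw", n = file.size(bed_path))
  if (length(raw) < 3 || !identical(raw[1:3], plink_magic))
    stop_input("not a PLINK 1 SNP-major bed file (bad magic bytes): ", bed_path)
  n_bytes <- ceiling(n / 4)
  if (length(raw) != 3 + n_bytes * p)
    stop_input("bed file size inconsistent with fam/bim dimensions")
  body <- matrix(as.integer(raw[-(1:3)]), nrow = n_bytes, ncol = p)
  g <- matrix(NA_integer_, n, p)
  for (j in seq_len(p)) {
    codes <- t(bed_decode_lut[body[, j] + 1L, , drop = FALSE])
    g[, j] <- codes[seq_len(n)]
  }
  phenotype <- NULL; covariates <- NULL
  if (!is.null(phenotype_table_path)) {
    sep <- if (grepl("\\.csv$", phenotype_table_path)) "," else "\t"
    tab <- utils::read.table(phenotype_table_path, header = TRUE, sep = sep,
                             stringsAsFactors = FALSE)
    if (!all(c("sample_id", "phenotype") %in% names(tab)))
      stop_input("phenotype table needs sample_id and phenotype columns")
    tab$sample_id <- as.character(tab$sample_id)
    keep <- sample_ids %in% tab$sample_id
    if (!any(keep)) stop_input("no overlapping sample ids between fam and table")
    g <- g[keep, , drop = FALSE]
    sample_ids <- sample_ids[keep]
    tab <- tab[match(sample_ids, tab$sample_id), , drop = FALSE]
    phenotype <- tab$phenotype
    covs <- setdiff(names(tab), c("sample_id", "phenotype"))
    if (length(covs))
      covariates <- as.matrix(tab[, covs, drop = FALSE])
  }
  genotype_dataset(g, bim[, c("snp_id", "chrom", "pos", "a1", "a2")],
                   sample_ids, phenotype = phenotype,
                   phenotype_kind = phenotype_kind, covariates = covariates)
}

#' Export split labels as TSV
#'
#' @param dataset A split-labelled [genotype_dataset()].
#' @param path Output TSV path (columns `sample_id`, `split`).
#' @export
write_splits <- function(dataset, path) {
  if (is.null(dataset$split)) stop_input("dataset has no split labels")
  utils::write.table(data.frame(sample_id = dataset$sample_ids,
                                split = dataset$split),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
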