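#' @keywords internal
"_PACKAGE"

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG stream.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

stop_input <- function(...) stop(..., call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Map chromosome labels to sortable indices (1..22, X=23, Y=24, XY=25,
# MT=26; anything else ordered after, by appearance).
chrom_index <- function(chrom) {
  ch <- toupper(as.character(chrom))
  idx <- suppressWarnings(as.integer(ch))
  special <- c(X = 23L, Y = 24L, XY = 25L, MT = 26L, M = 26L)
  hit <- ch %in% names(special)
  idx[hit] <- special[ch[hit]]
  if (anyNA(idx)) {
    other <- unique(ch[is.na(idx)])
    idx[is.na(idx)] <- 26L + match(ch[is.na(idx)], other)
  }
  idx
}

# Column means of a genotype matrix ignoring missing calls; constant for
# all-missing columns is 0.
train_impute_means <- function(g) {
  m <- colMeans(g, na.rm = TRUE)
  m[!is.finite(m)] <- 0
  m
}

# Replace missing entries column-wise by supplied means.
impute_by_means <- function(g, means) {
  idx <- which(is.na(g))
  if (length(idx)) {
    cols <- ((idx - 1L) %/% nrow(g)) + 1L
    g[idx] <- means[cols]
  }
  g
}
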