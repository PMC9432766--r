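# Integer compositions of total N into m nonnegative parts (lattice of the
# probability simplex at resolution 1/N), rows = points.
simplex_lattice <- function(m, N) {
  if (m == 1) return(matrix(N, 1, 1))
  out <- list()
  for (i in 0:N) {
    sub <- simplex_lattice(m - 1L, N - i)
    out[[length(out) + 1L]] <- cbind(i, sub)
  }
  do.call(rbind, out)
}

check_vectors <- function(prediction_vectors) {
  if (!is.list(prediction_vectors)) prediction_vectors <-
      lapply(seq_len(ncol(prediction_vectors)),
             function(j) prediction_vectors[, j])
  len <- lengths(prediction_vectors)
  if (length(prediction_vectors) < 2) stop_input("need at least 2 models")
  if (length(unique(len)) != 1) stop_input("prediction vectors differ in length")
  prediction_vectors
}

metric_function <- function(metric = c("r2", "auc")) {
  metric <- match.arg(metric)
  if (metric == "auc") auc else r_squared
}

#' Unweighted ensemble of prediction vectors
#'
#' @param prediction_vectors List (or matrix columns) of equal-length
#'   per-sample prediction vectors from at least two models.
#' @return Elementwise arithmetic mean.
#' @export
ensemble_unweighted <- function(prediction_vectors) {
  pv <- check_vectors(prediction_vectors)
  Reduce(`+`, pv) / length(pv)
}

#' Apply simplex weights to prediction vectors
#'
#' @param weights Nonnegative weights summing to 1, one per model (an
#'   `ensemble_weights` object or plain vector).
#' @param prediction_vectors As in [ensemble_unweighted()].
#' @return Weighted elementwise sum.
#' @export
apply_weights <- function(weights, prediction_vectors) {
  w <- if (inherits(weights, "ensemble_weights")) weights$weights else weights
  pv <- check_vectors(prediction_vectors)
  if (length(w) != length(pv)) stop_input("weight/model count mismatch")
  if (any(w < -1e-12) || abs(sum(w) - 1) > 1e-9)
    stop_input("weights must be nonnegative and sum to 1")
  Reduce(`+`, Map(`*`, as.list(w), pv))
}

check_targets <- function(targets, metric) {
  if (metric == "r2" && stats::sd(targets) == 0)
    stop_input("constant validation targets: r2 undefined")
  if (metric == "auc" && length(unique(targets)) < 2)
    stop_input("single-class validation targets: AUC undefined")
}

#' Validation-optimal ensemble weights on the probability simplex
#'
#' Exhaustively evaluates the validation metric at every point of the
#' simplex lattice with step `grid_resolution` and returns the maximizing
#' weights. The lattice contains all vertices, so the achieved validation
#' metric is never below any individual model's. Ties are resolved toward
#' the uniform point. For more than four models the exhaustive scan is
#' replaced by coordinate-wise refinement from the uniform point.
#'
#' @param prediction_vectors Validation-set prediction vectors, one per
#'   model.
#' @param validation_targets Observed validation outcomes.
#' @param metric `"r2"` or `"auc"`, matching the phenotype kind.
#' @param grid_resolution Lattice step (default 0.01).
#' @return An object of class `ensemble_weights` with `weights`,
#'   `validation_metric` and `grid_resolution`.
#' @export
fit_ensemble_weights <- function(prediction_vectors, validation_targets,
                                 metric = c("r2", "auc"),
                                 grid_resolution = 0.01) {
  metric <- match.arg(metric)
  pv <- check_vectors(prediction_vectors)
  check_targets(validation_targets, metric)
  mf <- metric_function(metric)
  m <- length(pv)
  N <- max(1L, round(1 / grid_resolution))
  pmat <- do.call(cbind, pv)
  if (m <= 4) {
    lat <- simplex_lattice(m, N) / N
    vals <- apply(lat, 1, function(w) mf(validation_targets,
                                         as.numeric(pmat %*% w)))
    best <- max(vals)
    cand <- which(vals >= best - 1e-12)
    # tie-break toward the uniform point
    d2 <- rowSums((lat[cand, , drop = FALSE] - 1 / m)^2)
    w <- lat[cand[which.min(d2)], ]
  } else {
    w <- rep(1 / m, m)
    cur <- mf(validation_targets, as.numeric(pmat %*% w))
    step <- 1 / N
    repeat {
      improved <- FALSE
      for (i in seq_len(m)) for (j in seq_len(m)) {
        if (i == j || w[i] < step) next
        w2 <- w; w2[i] <- w2[i] - step; w2[j] <- w2[j] + step
        v2 <- mf(validation_targets, as.numeric(pmat %*% w2))
        if (v2 > cur + 1e-12) { w <- w2; cur <- v2; improved <- TRUE }
      }
      if (!improved) break
    }
    # vertices are always candidates, preserving validation dominance
    for (j in seq_len(m)) {
      wv <- rep(0, m); wv[j] <- 1
      vv <- mf(validation_targets, as.numeric(pmat %*% wv))
      if (vv > cur + 1e-12) { w <- wv; cur <- vv }
    }
    best <- cur
  }
  structure(list(weights = as.numeric(w), validation_metric = best,
                 grid_resolution = 1 / N, metric = metric),
            class = "ensemble_weights")
}

#' @export
print.ensemble_weights <- function(x, ...) {
  cat("ensemble_weights:", paste(round(x$weights, 3), collapse = " / "),
      "|", x$metric, "=", round(x$validation_metric, 4),
      "(grid", x$grid_resolution, ")\n")
  invisible(x)
}

#' Metric surface over the 3-model simplex lattice
#'
#' Evaluates the metric at every lattice point for exactly three models,
#' yielding the table behind a ternary (barycentric) heatmap of ensemble
#' performance. Vertex rows equal the individual model metrics; the center
#' row equals the unweighted ensemble.
#'
#' @inheritParams fit_ensemble_weights
#' @return Data frame with columns `w1`, `w2`, `w3`, `metric`.
#' @export
simplex_grid_metrics <- function(prediction_vectors, targets,
                                 metric = c("r2", "auc"),
                                 grid_resolution = 0.01) {
  metric <- match.arg(metric)
  pv <- check_vectors(prediction_vectors)
  if (length(pv) != 3) stop_input("simplex_grid_metrics expects exactly 3 models")
  check_targets(targets, metric)
  mf <- metric_function(metric)
  N <- max(1L, round(1 / grid_resolution))
  lat <- simplex_lattice(3L, N) / N
  pmat <- do.call(cbind, pv)
  vals <- apply(lat, 1, function(w) mf(targets, as.numeric(pmat %*% w)))
  data.frame(w1 = lat[, 1], w2 = lat[, 2], w3 = lat[, 3], metric = vals)
}
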