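#' Collapse probes to genes by maximal variability
#'
#' Builds the one-probe-to-one-gene relational model: for every gene, the
#' probe with the highest sample standard deviation (denominator n-1) is
#' kept and relabeled to the gene id; remaining probes are discarded.
#' Ties are broken toward the lexicographically smallest probe id so the
#' result is deterministic.  Probes absent from the map are dropped and
#' logged.  Output rows are ordered by gene id.
#'
#' @param ds a probe-level [expression_dataset()] (a gene-level dataset
#'   passes through if the map is an identity on its genes).
#' @param map data.frame with columns `probe_id`, `gene_id`
#'   (see [read_probe_map()]).
#' @return a gene-level [expression_dataset()].
#' @export
collapse_probes_max_sd <- function(ds, map) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  probes <- rownames(ds$values)
  map <- map[map$probe_id %in% probes, , drop = FALSE]
  if (nrow(map) == 0) cx_stop("no overlap between dataset probes and probe map")
  n_unmapped <- sum(!probes %in% map$probe_id)
  if (n_unmapped > 0) cx_log("dropping ", n_unmapped, " unmapped probe(s)")

  sds <- apply(ds$values[map$probe_id, , drop = FALSE], 1, stats::sd)
  ord <- order(map$gene_id, -sds, map$probe_id)  # per gene: max SD, then id
  map_o <- map[ord, , drop = FALSE]
  keep <- map_o[!duplicated(map_o$gene_id), , drop = FALSE]

  values <- ds$values[keep$probe_id, , drop = FALSE]
  rownames(values) <- keep$gene_id
  expression_dataset(values, ds$dataset_id, ds$platform_id,
                     unname(ds$sample_groups), ds$tumor_content,
                     feature_level = "gene")
}

#' Quantile normalization
#'
#' Forces every sample (column) onto the same empirical distribution: the
#' reference is the row-wise mean of the column-sorted matrix, and each
#' value is replaced by the reference value at its rank.  Ties receive the
#' mean of the corresponding reference values (average ranks interpolated
#' linearly on the reference).
#'
#' @param values numeric matrix, features x samples (>= 2 samples).
#' @return normalized matrix with identical sorted columns.
#' @export
quantile_normalize <- function(values) {
  values <- as.matrix(values)
  assert_that(ncol(values) >= 2, "quantile normalization needs >= 2 samples")
  n <- nrow(values)
  if (n == 0) return(values)
  ref <- rowMeans(apply(values, 2, sort))
  out <- values
  for (j in seq_len(ncol(values))) {
    rk <- rank(values[, j], ties.method = "average")
    out[, j] <- if (n == 1) ref else stats::approx(seq_len(n), ref, xout = rk)$y
  }
  out
}

#' Log-CPM transform with mean-variance precision weights
#'
#' Transforms read counts to log2 counts-per-million,
#' `log2((count + 0.5) / (lib_size + 1) * 1e6)`, then models the
#' mean-variance relationship of log-counts: per-gene square-root residual
#' standard deviations are smoothed against mean log2-counts with lowess
#' (span 0.5), and per-observation weights are the inverse of the fourth
#' power of the trend evaluated at each observation's fitted log-count.
#' The trend is extrapolated linearly beyond the fitted range and floored
#' away from zero so weights stay finite and strictly positive.
#'
#' @param counts non-negative integer matrix, genes x samples.
#' @param lib_sizes per-sample library sizes (default column sums).
#' @param groups optional two-level grouping used for the residual fit;
#'   default a single intercept.  Each modeled group needs >= 2 samples.
#' @param span lowess span for the trend (default 0.5).
#' @return list with `logcpm` and `weights` matrices (same dim as counts)
#'   and the fitted trend (`trend_x`, `trend_y`).
#' @export
voom_transform <- function(counts, lib_sizes = colSums(counts), groups = NULL,
                           span = 0.5) {
  counts <- as.matrix(counts)
  assert_that(all(counts >= 0), "counts must be non-negative")
  assert_that(all(lib_sizes > 0), "library sizes must be positive")
  assert_that(ncol(counts) >= 2, "voom needs >= 2 samples")
  n <- ncol(counts)

  logcpm <- log2(sweep(counts + 0.5, 2, lib_sizes + 1, "/") * 1e6)
  dimnames(logcpm) <- dimnames(counts)

  if (is.null(groups)) {
    groups <- factor(rep("all", n))
  } else {
    groups <- factor(groups)
    assert_that(all(table(groups) >= 2), "each modeled group needs >= 2 samples")
  }

  ## Per-gene fitted values and residual SD under the group-means model
  fitted <- matrix(0, nrow(counts), n)
  rss <- numeric(nrow(counts))
  df_res <- n - nlevels(groups)
  assert_that(df_res >= 1, "no residual degrees of freedom for the trend fit")
  for (lev in levels(groups)) {
    idx <- which(groups == lev)
    m <- rowMeans(logcpm[, idx, drop = FALSE])
    fitted[, idx] <- m
    rss <- rss + rowSums((logcpm[, idx, drop = FALSE] - m)^2)
  }
  sigma <- sqrt(rss / df_res)

  ## Trend on the log2-count scale: mean log2 count vs sqrt residual SD
  mean_lcpm <- rowMeans(logcpm)
  sx <- mean_lcpm + mean(log2(lib_sizes + 1)) - log2(1e6)
  sy <- sqrt(sigma)
  lo <- stats::lowess(sx, sy, f = span)

  ## Evaluate trend at per-observation fitted log-counts, linear
  ## extrapolation outside the fitted range
  fitted_count <- fitted + matrix(log2(lib_sizes + 1), nrow(counts), n,
                                  byrow = TRUE) - log2(1e6)
  pred <- trend_eval(lo$x, lo$y, as.vector(fitted_count))
  pred <- pmax(pred, 1e-6)  # floor keeps weights finite
  weights <- matrix(1 / pred^4, nrow(counts), n)
  dimnames(weights) <- dimnames(counts)

  list(logcpm = logcpm, weights = weights, trend_x = lo$x, trend_y = lo$y)
}

## Piecewise-linear interpolation with linear extrapolation at both ends.
trend_eval <- function(x, y, xout) {
  keep <- !duplicated(x)
  x <- x[keep]; y <- y[keep]
  if (length(x) == 1) return(rep(y, length(xout)))
  out <- stats::approx(x, y, xout = xout, rule = 2)$y
  n <- length(x)
  lo_slope <- (y[2] - y[1]) / (x[2] - x[1])
  hi_slope <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
  below <- xout < x[1]
  above <- xout > x[n]
  out[below] <- y[1] + lo_slope * (xout[below] - x[1])
  out[above] <- y[n] + hi_slope * (xout[above] - x[n])
  out
}
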