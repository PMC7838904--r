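#' Integrative correlation coefficients across platforms
#'
#' For each pair of platforms and each shared gene `g`, the gene's
#' within-platform correlation profile — the vector of Pearson
#' correlations between `g` and every other shared gene — is computed in
#' both platforms, and the pair ICC is the Pearson correlation of the two
#' profiles.  A gene whose expression pattern is reproducible across
#' platforms has profiles that agree (ICC near 1).  Per-gene,
#' per-platform summaries average the pairwise ICCs involving that
#' platform; genes measured on a single platform get ICC 0 by convention
#' (they carry no cross-platform reproducibility evidence).
#'
#' @param mats named list (one entry per platform) of gene x sample
#'   numeric matrices with gene row names.  Every platform pair must
#'   share >= 3 genes.  Zero-variance genes get ICC 0 (logged).
#' @return an `ICCTable` list: `pairs` (long data.frame gene /
#'   platform_a / platform_b / r), `per_platform` (gene x platform matrix
#'   of platform-level ICC summaries), `icc` (named per-gene mean over
#'   all pairs).
#' @export
integrative_correlation <- function(mats) {
  assert_that(is.list(mats) && length(mats) >= 2, "need >= 2 platforms")
  if (is.null(names(mats))) names(mats) <- paste0("platform", seq_along(mats))
  platforms <- names(mats)
  all_genes <- sort(unique(unlist(lapply(mats, rownames))))

  ## one gene-gene correlation matrix per platform (pairwise gene
  ## correlations do not depend on the shared universe, so pair blocks
  ## are plain subsets)
  corr <- lapply(mats, function(A) {
    A <- as.matrix(A)
    ctr <- A - rowMeans(A)
    ss <- sqrt(rowSums(ctr^2))
    degenerate <- ss == 0 | !is.finite(ss)
    if (any(degenerate)) {
      cx_log(sum(degenerate), " zero-variance gene(s); their ICC set to 0")
    }
    ss[degenerate] <- 1
    C <- tcrossprod(ctr / ss)  # unit rows: diagonal is already 1
    if (any(degenerate)) {
      C[degenerate, ] <- 0
      C[, degenerate] <- 0
      diag(C) <- 1
    }
    list(C = C, degenerate = stats::setNames(degenerate, rownames(A)))
  })

  pair_rows <- list()
  for (i in seq_len(length(mats) - 1)) {
    for (j in seq(i + 1, length(mats))) {
      shared <- intersect(rownames(mats[[i]]), rownames(mats[[j]]))
      assert_that(length(shared) >= 3,
                  "platform pair shares fewer than 3 genes")
      r <- pair_icc(corr[[i]]$C[shared, shared, drop = FALSE],
                    corr[[j]]$C[shared, shared, drop = FALSE],
                    corr[[i]]$degenerate[shared] | corr[[j]]$degenerate[shared])
      pair_rows[[length(pair_rows) + 1]] <- data.frame(
        gene = shared, platform_a = platforms[i], platform_b = platforms[j],
        r = r, stringsAsFactors = FALSE
      )
    }
  }
  pairs <- do.call(rbind, pair_rows)

  per_platform <- matrix(NA_real_, length(all_genes), length(platforms),
                         dimnames = list(all_genes, platforms))
  for (p in platforms) {
    sub <- pairs[pairs$platform_a == p | pairs$platform_b == p, , drop = FALSE]
    if (nrow(sub) > 0) {
      agg <- tapply(sub$r, sub$gene, mean)
      per_platform[names(agg), p] <- as.numeric(agg)
    }
  }
  icc_all <- tapply(pairs$r, pairs$gene, mean)
  icc <- stats::setNames(rep(0, length(all_genes)), all_genes)
  icc[names(icc_all)] <- as.numeric(icc_all)

  structure(list(pairs = pairs, per_platform = per_platform, icc = icc),
            class = "ICCTable")
}

## Vectorized pair ICC: rowwise Pearson correlation between the two
## gene-gene correlation matrices, excluding the diagonal (self term).
pair_icc <- function(CA, CB, degenerate = rep(FALSE, nrow(CA))) {
  m <- nrow(CA)
  n <- m - 1
  sA <- rowSums(CA) - diag(CA)
  sB <- rowSums(CB) - diag(CB)
  sAB <- rowSums(CA * CB) - diag(CA) * diag(CB)
  sA2 <- rowSums(CA^2) - diag(CA)^2
  sB2 <- rowSums(CB^2) - diag(CB)^2
  num <- n * sAB - sA * sB
  den <- sqrt(pmax(n * sA2 - sA^2, 0) * pmax(n * sB2 - sB^2, 0))
  r <- ifelse(den > 0, num / den, 0)
  r[degenerate] <- 0
  pmin(pmax(r, -1), 1)
}

#' Platform weight for the Stouffer combination
#'
#' `W = |log2FC| + |log2FC| * ICC^2 = |log2FC| * (1 + ICC^2)`: the weight
#' grows with effect magnitude and with cross-platform reproducibility,
#' and satisfies `|log2FC| <= W <= 2 |log2FC|`.
#'
#' @param log2fc log2 fold change(s).
#' @param icc integrative correlation coefficient(s) in \[-1, 1\].
#' @return non-negative weight(s), vectorized.
#' @export
stouffer_weight <- function(log2fc, icc) {
  assert_that(all(icc >= -1 & icc <= 1), "ICC must lie in [-1, 1]")
  abs(log2fc) * (1 + icc^2)
}

#' Combine per-platform differential expression by weighted Stouffer
#'
#' Each platform's two-sided p-value becomes a signed Z,
#' `Z_i = sign(log2FC_i) * qnorm(1 - p_i / 2)`, and the platforms are
#' combined as `Z = sum(W_i Z_i) / sqrt(sum(W_i^2))` with
#' `W_i = |log2FC_i| * (1 + ICC_i^2)` (see [stouffer_weight()]).  Every
#' gene is combined over exactly the platforms where it was measured, so
#' genes covered by a single platform are retained rather than lost.
#' Combined two-sided p-values are BH-adjusted and ranked (ascending p,
#' ties by descending mean |log2FC|, then gene id).
#'
#' Genes whose weights are all zero get `Z = 0`, `p = 1` (logged);
#' `p_i = 0` is clamped to the smallest positive double.
#'
#' @param de list of `DEResult` tables from [moderated_t()], one per
#'   platform (names used as platform ids if set).
#' @param icc an `ICCTable` from [integrative_correlation()], or `NULL`
#'   for a single platform (ICC 0 is then used throughout).
#' @return an `IntegrationResult` data.frame with columns `gene`,
#'   `n_platforms`, `z_combined`, `p_combined`, `q`, `rank`, and
#'   attributes `z_matrix`, `w_matrix`, `fc_matrix` (gene x platform).
#' @export
combine_platforms <- function(de, icc = NULL) {
  assert_that(is.list(de) && length(de) >= 1, "need >= 1 DEResult")
  if (is.null(names(de)) || any(!nzchar(names(de)))) {
    names(de) <- vapply(seq_along(de), function(i) {
      pid <- attr(de[[i]], "platform_id")
      if (is.null(pid) || is.na(pid)) paste0("platform", i) else pid
    }, character(1))
  }
  platforms <- names(de)
  genes <- sort(unique(unlist(lapply(de, function(d) d$gene))))
  nG <- length(genes)
  nP <- length(platforms)

  Z <- W <- FC <- matrix(NA_real_, nG, nP, dimnames = list(genes, platforms))
  for (p in seq_len(nP)) {
    d <- de[[p]]
    pv <- pmax(d$p, .Machine$double.xmin)
    if (any(d$p < .Machine$double.xmin)) {
      cx_log("clamped ", sum(d$p < .Machine$double.xmin),
             " zero p-value(s) on platform ", platforms[p])
    }
    z <- sign(d$log2fc) * stats::qnorm(pv / 2, lower.tail = FALSE)
    z[d$log2fc == 0] <- 0
    Z[d$gene, p] <- z
    FC[d$gene, p] <- d$log2fc
    icc_p <- rep(0, nrow(d))
    if (!is.null(icc) && platforms[p] %in% colnames(icc$per_platform)) {
      hit <- intersect(d$gene, rownames(icc$per_platform))
      v <- icc$per_platform[hit, platforms[p]]
      v[is.na(v)] <- 0
      icc_p[match(hit, d$gene)] <- v
    }
    W[d$gene, p] <- stouffer_weight(d$log2fc, icc_p)
  }

  present <- !is.na(Z)
  n_platforms <- rowSums(present)
  W0 <- ifelse(present, W, 0)
  Z0 <- ifelse(present, Z, 0)
  denom <- sqrt(rowSums(W0^2))
  z_comb <- ifelse(denom > 0, rowSums(W0 * Z0) / denom, 0)
  all_zero <- denom == 0
  if (any(all_zero)) {
    cx_log(sum(all_zero), " gene(s) with all-zero weights: Z = 0, p = 1")
  }
  p_comb <- 2 * stats::pnorm(-abs(z_comb))
  p_comb[all_zero] <- 1
  p_comb <- pmax(p_comb, .Machine$double.xmin)
  q <- bh_adjust(p_comb)

  mean_abs_fc <- rowMeans(abs(FC), na.rm = TRUE)
  ord <- order(p_comb, -mean_abs_fc, genes)
  rnk <- integer(nG)
  rnk[ord] <- seq_len(nG)

  res <- data.frame(
    gene = genes, n_platforms = as.integer(n_platforms),
    z_combined = unname(z_comb), p_combined = unname(p_comb),
    q = unname(q), rank = rnk, stringsAsFactors = FALSE
  )
  attr(res, "z_matrix") <- Z
  attr(res, "w_matrix") <- W
  attr(res, "fc_matrix") <- FC
  attr(res, "comparison") <- attr(de[[1]], "comparison")
  class(res) <- c("IntegrationResult", "data.frame")
  res
}

#' Integration-driven discovery rate curve
#'
#' At each Z threshold, the IDR is the fraction of combined-significant
#' genes (`|Z_combined| >= z`) that no contributing platform detects on
#' its own (`|Z_i| < z` for every platform where the gene was measured) —
#' the discoveries owed to integration.  An empty denominator yields
#' IDR 0.
#'
#' @param res an `IntegrationResult` from [combine_platforms()].
#' @param z_grid vector of Z thresholds (default `seq(0, 8, 0.1)`).
#' @return an `IDRCurve` data.frame with columns `z`,
#'   `n_combined_significant`, `n_exclusive`, `idr`.
#' @export
idr_curve <- function(res, z_grid = seq(0, 8, by = 0.1)) {
  Z <- attr(res, "z_matrix")
  assert_that(!is.null(Z), "result lacks per-platform Z matrix")
  zc <- abs(res$z_combined)
  maxZi <- apply(abs(Z), 1, max, na.rm = TRUE)
  out <- data.frame(z = z_grid)
  out$n_combined_significant <- vapply(z_grid, function(z) sum(zc >= z), 0L)
  out$n_exclusive <- vapply(z_grid, function(z) sum(zc >= z & maxZi < z), 0L)
  out$idr <- ifelse(out$n_combined_significant > 0,
                    out$n_exclusive / out$n_combined_significant, 0)
  class(out) <- c("IDRCurve", "data.frame")
  out
}

#' Cross-dataset concordance curve
#'
#' For each cumulative top-k of the combined ranking, the fraction of
#' genes that are consistently deregulated across datasets: a gene
#' qualifies if `log2FC > fc_cut` in at least half of the datasets
#' (rounded up), or `log2FC < -fc_cut` in at least half — one common
#' direction is required.
#'
#' @param res an `IntegrationResult`.
#' @param fc_tables named list (one per dataset) of named numeric
#'   vectors: per-gene log2 fold changes in that dataset.  Needs >= 2
#'   datasets.
#' @param k_grid vector of list sizes (default `seq(50, 2000, 50)`);
#'   values above the gene count are truncated to it.
#' @param fc_cut fold-change cut, default 1 (i.e. two-fold).
#' @return a `ConcordanceCurve` data.frame with columns `k`, `fraction`.
#' @export
concordance_curve <- function(res, fc_tables, k_grid = seq(50, 2000, by = 50),
                              fc_cut = 1) {
  assert_that(is.list(fc_tables) && length(fc_tables) >= 2,
              "concordance needs >= 2 datasets")
  n_ds <- length(fc_tables)
  need <- ceiling(n_ds / 2)
  genes <- res$gene
  up <- dn <- matrix(FALSE, length(genes), n_ds)
  for (j in seq_len(n_ds)) {
    v <- fc_tables[[j]]
    hit <- genes %in% names(v)
    up[hit, j] <- v[genes[hit]] > fc_cut
    dn[hit, j] <- v[genes[hit]] < -fc_cut
  }
  concordant <- rowSums(up) >= need | rowSums(dn) >= need
  ord_genes <- order(res$rank)
  conc_sorted <- concordant[ord_genes]
  csum <- cumsum(conc_sorted)
  kk <- pmin(k_grid, length(genes))
  out <- data.frame(
    k = k_grid,
    fraction = ifelse(kk > 0, csum[kk] / kk, 0)
  )
  attr(out, "comparison") <- attr(res, "comparison")
  class(out) <- c("ConcordanceCurve", "data.frame")
  out
}

#' Select the hallmark list size from concordance curves
#'
#' Operationalizes "the point where the curves cross": returns the grid k
#' minimizing the spread (max - min) of the comparisons' concordance
#' fractions, so each stage's top-k carries a similar fraction of
#' consistently deregulated genes.  With a single curve, or when every k
#' has the same spread, the default (500) is returned.  Ties among
#' minimizers go to the k closest to `default_k`, then the smaller k.
#'
#' @param curves list of `ConcordanceCurve` objects on a common `k` grid.
#' @param default_k fallback list size, default 500.
#' @return selected k (integer).
#' @export
select_top_k <- function(curves, default_k = 500) {
  assert_that(length(curves) >= 1, "need >= 1 concordance curve")
  k_grid <- curves[[1]]$k
  assert_that(length(k_grid) > 0, "empty k grid")
  if (length(curves) == 1) return(default_k)
  for (cv in curves) assert_that(identical(cv$k, k_grid),
                                 "curves must share the k grid")
  fr <- vapply(curves, function(cv) cv$fraction, numeric(length(k_grid)))
  spread <- apply(fr, 1, max) - apply(fr, 1, min)
  if (diff(range(spread)) == 0) return(default_k)
  cand <- which(spread == min(spread))
  cand <- cand[order(abs(k_grid[cand] - default_k), k_grid[cand])]
  as.integer(k_grid[cand[1]])
}
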