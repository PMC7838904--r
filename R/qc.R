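#' Filter tumor-bearing samples by tumor-tissue content
#'
#' Bulk resection samples are cell-type admixtures; low tumor content
#' dilutes the tumor signal.  Tumor-bearing samples (`primary_tumor`,
#' `metastatic_primary_tumor`, `metastasis`) with known content below the
#' threshold are removed.  The bound is inclusive: content equal to the
#' threshold passes ("minimum acceptable" content).  Control and HGPIN
#' samples, and samples with unknown content, always pass.
#'
#' @param ds an [expression_dataset()].
#' @param threshold minimum acceptable tumor fraction, default 0.40.
#' @return the filtered dataset.
#' @export
filter_by_tumor_content <- function(ds, threshold = 0.40) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  assert_that(threshold >= 0 && threshold <= 1, "threshold must be in [0, 1]")
  is_tumor <- ds$sample_groups %in% TUMOR_BEARING_GROUPS
  if (is.null(ds$tumor_content)) {
    cx_log("tumor content unknown for all samples; none removed")
    return(ds)
  }
  tc <- ds$tumor_content
  drop <- is_tumor & !is.na(tc) & tc < threshold
  n_unknown <- sum(is_tumor & is.na(tc))
  if (n_unknown > 0) {
    cx_log(n_unknown, " tumor sample(s) with unknown content retained")
  }
  cx_log("removing ", sum(drop), "/", sum(is_tumor),
         " tumor-bearing sample(s) below content ", threshold)
  out <- subset_samples(ds, !drop)
  if (ncol(out$values) == 0) {
    cx_stop("no samples remain after tumor-content filtering")
  }
  if (any(is_tumor) && !any(out$sample_groups %in% TUMOR_BEARING_GROUPS)) {
    cx_stop("all tumor-bearing samples fall below tumor-content threshold ",
            threshold)
  }
  out
}

#' Remove stroma-associated genes
#'
#' Drops the union of one or more stromal gene lists from the matrix, so
#' that downstream signatures are epithelial/tumor-specific rather than
#' driven by stromal admixture.  List entries absent from the matrix are
#' ignored (logged).
#'
#' @param ds a gene-level [expression_dataset()].
#' @param gene_lists a character vector of file paths (read with
#'   [read_gene_list()]) or a list of character vectors of gene ids.
#' @return the dataset without the listed genes.
#' @export
remove_stromal_genes <- function(ds, gene_lists) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  assert_that(ds$feature_level == "gene",
              "stromal filtering requires a gene-level dataset")
  if (is.character(gene_lists)) gene_lists <- lapply(gene_lists, read_gene_list)
  if (!is.list(gene_lists)) gene_lists <- list(gene_lists)
  for (i in seq_along(gene_lists)) {
    cx_log("stromal list ", i, ": ", length(unique(gene_lists[[i]])), " genes")
  }
  drop_union <- unique(unlist(gene_lists))
  present <- intersect(drop_union, rownames(ds$values))
  cx_log("stromal union: ", length(drop_union), " genes, ",
         length(present), " present in matrix and removed")
  subset_features(ds, !(rownames(ds$values) %in% drop_union))
}

#' Flag outlier samples on leading principal components
#'
#' Robust stand-in for multivariate array-outlier detection: a sample is
#' flagged when its score on any of the first `n_components` principal
#' components lies more than `mad_multiplier` MADs from that component's
#' median.  Components with (near-)zero variance are skipped, so a matrix
#' of identical samples yields no flags.  Deterministic and invariant to
#' sample order and to global additive shifts.
#'
#' @param ds an [expression_dataset()].
#' @param n_components number of leading components to inspect (default 3).
#' @param mad_multiplier robust-deviation multiplier (default 4).
#' @return named logical vector, `TRUE` = flagged outlier.
#' @export
pca_outlier_flags <- function(ds, n_components = 3, mad_multiplier = 4) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  n <- ncol(ds$values)
  assert_that(n >= 3, "PCA outlier detection needs >= 3 samples")
  assert_that(n_components >= 1 &&
                n_components <= min(dim(ds$values)),
              "n_components must be in [1, min(features, samples)]")
  x <- t(ds$values - rowMeans(ds$values))
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  flags <- rep(FALSE, n)
  tot_sd <- sqrt(sum(pc$sdev^2))
  for (j in seq_len(k)) {
    if (pc$sdev[j] < 1e-8 * max(tot_sd, 1e-300)) next  # degenerate component
    s <- pc$x[, j]
    med <- stats::median(s)
    dev <- stats::mad(s)
    if (dev == 0) next
    flags <- flags | (abs(s - med) > mad_multiplier * dev)
  }
  stats::setNames(flags, colnames(ds$values))
}

#' Compare biological against dataset (laboratory) effects
#'
#' Builds two distributions of pairwise sample similarities over the
#' shared-gene intersection: (i) pairs from the same biological group but
#' different datasets ("biological signal survives the lab"), and (ii)
#' pairs from the same dataset but different groups ("lab signal crosses
#' biology").  Similarity is the Pearson correlation of the two samples'
#' expression profiles.  A two-sample Kolmogorov-Smirnov test compares the
#' distributions; biology is declared stronger when the median same-group
#' cross-dataset similarity exceeds the median same-dataset cross-group
#' similarity and the KS p-value is below `alpha`.
#'
#' @param datasets list of gene-level [expression_dataset()] objects
#'   (>= 2) sharing >= 2 biological groups and >= 10 genes.
#' @param alpha significance level for the KS test (default 0.05).
#' @return an `EffectStrengthReport` list with both similarity vectors,
#'   `ks_statistic`, `ks_pvalue`, and `biological_stronger`.
#' @export
effect_strength_assessment <- function(datasets, alpha = 0.05) {
  assert_that(length(datasets) >= 2, "need >= 2 datasets")
  shared <- Reduce(intersect, lapply(datasets, function(d) rownames(d$values)))
  assert_that(length(shared) >= 10, "datasets must share >= 10 genes")
  groups_per <- lapply(datasets, function(d) unique(d$sample_groups))
  shared_groups <- Reduce(intersect, groups_per)
  assert_that(length(shared_groups) >= 2,
              "datasets must share >= 2 biological groups")

  big <- do.call(cbind, lapply(datasets, function(d) d$values[shared, , drop = FALSE]))
  ds_id <- unlist(lapply(datasets, function(d) rep(d$dataset_id, ncol(d$values))))
  grp <- unlist(lapply(datasets, function(d) unname(d$sample_groups)))
  cc <- stats::cor(big)

  n <- ncol(big)
  idx <- which(upper.tri(cc), arr.ind = TRUE)
  same_group <- grp[idx[, 1]] == grp[idx[, 2]]
  same_ds <- ds_id[idx[, 1]] == ds_id[idx[, 2]]
  sims <- cc[idx]
  wg_cd <- sims[same_group & !same_ds]   # biological signal, across labs
  wd_cg <- sims[!same_group & same_ds]   # lab signal, across biology
  assert_that(length(wg_cd) > 0, "no same-group cross-dataset pairs")
  assert_that(length(wd_cg) > 0, "no same-dataset cross-group pairs")

  ks <- suppressWarnings(stats::ks.test(wg_cd, wd_cg))
  structure(
    list(
      within_group_cross_dataset_sims = wg_cd,
      within_dataset_cross_group_sims = wd_cg,
      ks_statistic = unname(ks$statistic),
      ks_pvalue = ks$p.value,
      biological_stronger =
        stats::median(wg_cd) > stats::median(wd_cg) && ks$p.value < alpha,
      alpha = alpha
    ),
    class = "EffectStrengthReport"
  )
}

#' @export
print.EffectStrengthReport <- function(x, ...) {
  cat(sprintf(
    paste0("EffectStrengthReport: KS D = %.3f, p = %.3g\n",
           "  median similarity same-group/cross-dataset: %.3f (n = %d)\n",
           "  median similarity same-dataset/cross-group: %.3f (n = %d)\n",
           "  biological effects stronger than dataset effects: %s\n"),
    x$ks_statistic, x$ks_pvalue,
    stats::median(x$within_group_cross_dataset_sims),
    length(x$within_group_cross_dataset_sims),
    stats::median(x$within_dataset_cross_group_sims),
    length(x$within_dataset_cross_group_sims),
    x$biological_stronger
  ))
  invisible(x)
}
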