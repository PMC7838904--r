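#' Construct an ExpressionDataset
#'
#' Container for one study's feature-by-sample expression matrix together
#' with its platform/dataset annotations.  Array intensities are expected
#' on the log2 scale and sequencing data as log-CPM (see
#' [voom_transform()]); downstream operations assume log-scale input.
#'
#' @param values numeric matrix, features in rows, samples in columns.
#'   Row names are feature ids (probe or gene), column names sample ids.
#' @param dataset_id,platform_id single strings identifying the study and
#'   the measurement platform.
#' @param sample_groups character vector, one biological group label per
#'   sample, from the closed vocabulary `normal`, `BPH`, `NAD`, `HGPIN`,
#'   `primary_tumor`, `metastatic_primary_tumor`, `metastasis` (plus
#'   `control` after [merge_control_groups()]).
#' @param tumor_content optional numeric vector of per-sample tumor-tissue
#'   fractions in \[0, 1\]; `NA` marks unknown content.
#' @param feature_level `"probe"` or `"gene"`.
#' @return object of class `ExpressionDataset`.
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'   dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' ds <- expression_dataset(m, "dsA", "platA",
#'   c("normal", "normal", "primary_tumor", "primary_tumor"))
#' @export
expression_dataset <- function(values, dataset_id, platform_id, sample_groups,
                               tumor_content = NULL,
                               feature_level = c("gene", "probe")) {
  feature_level <- match.arg(feature_level)
  values <- as.matrix(values)
  assert_that(is.numeric(values), "expression values must be numeric")
  assert_that(!is.null(rownames(values)) && !is.null(colnames(values)),
              "values must carry feature ids (rownames) and sample ids (colnames)")
  assert_that(length(sample_groups) == ncol(values),
              "one group label required per sample")
  bad <- setdiff(unique(sample_groups), GROUP_LEVELS)
  if (length(bad) > 0) {
    cx_stop("unknown group label(s): ", paste(sQuote(bad), collapse = ", "),
            "; allowed: ", paste(GROUP_LEVELS, collapse = ", "))
  }
  assert_that(!anyDuplicated(colnames(values)), "duplicate sample ids")
  if (feature_level == "gene") {
    assert_that(!anyDuplicated(rownames(values)),
                "duplicate feature ids at gene level")
  }
  if (!is.null(tumor_content)) {
    assert_that(length(tumor_content) == ncol(values),
                "one tumor_content value required per sample")
    ok <- is.na(tumor_content) | (tumor_content >= 0 & tumor_content <= 1)
    assert_that(all(ok), "tumor_content must lie in [0, 1] (or NA)")
  }
  structure(
    list(
      dataset_id = as.character(dataset_id)[1],
      platform_id = as.character(platform_id)[1],
      values = values,
      sample_groups = stats::setNames(as.character(sample_groups), colnames(values)),
      tumor_content = if (is.null(tumor_content)) NULL else
        stats::setNames(as.numeric(tumor_content), colnames(values)),
      feature_level = feature_level
    ),
    class = "ExpressionDataset"
  )
}

#' @export
print.ExpressionDataset <- function(x, ...) {
  cat(sprintf(
    "ExpressionDataset '%s' (platform '%s'): %d %ss x %d samples\n",
    x$dataset_id, x$platform_id, nrow(x$values), x$feature_level,
    ncol(x$values)
  ))
  tab <- table(x$sample_groups)
  cat("  groups:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  if (!is.null(x$tumor_content)) {
    cat(sprintf("  tumor_content known for %d/%d samples\n",
                sum(!is.na(x$tumor_content)), ncol(x$values)))
  }
  invisible(x)
}

#' @export
dim.ExpressionDataset <- function(x) dim(x$values)

subset_samples <- function(ds, keep) {
  ds$values <- ds$values[, keep, drop = FALSE]
  ds$sample_groups <- ds$sample_groups[keep]
  if (!is.null(ds$tumor_content)) ds$tumor_content <- ds$tumor_content[keep]
  ds
}

subset_features <- function(ds, keep) {
  ds$values <- ds$values[keep, , drop = FALSE]
  ds
}

#' Pool the non-malignant groups into a single control group
#'
#' Histologically non-malignant tissues (normal, benign hyperplasia, and
#' normal-adjacent-to-tumor) are molecularly much closer to each other than
#' to tumor, so they are pooled into one `control` group before
#' differential expression.  Matrix values and sample count are untouched;
#' only labels change.  Idempotent.
#'
#' @param ds an [expression_dataset()].
#' @return the dataset with `normal`/`BPH`/`NAD` relabeled `control`.
#' @export
merge_control_groups <- function(ds) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  idx <- ds$sample_groups %in% CONTROL_LIKE_GROUPS
  ds$sample_groups[idx] <- "control"
  ds
}

#' Define a two-group comparison
#'
#' @param name comparison name, e.g. `"tumor_vs_normal"`.
#' @param case_group,control_group group label(s); sets are allowed
#'   (samples from any listed label are pooled).
#' @return object of class `Comparison`.
#' @export
comparison <- function(name, case_group, control_group) {
  assert_that(length(case_group) >= 1 && length(control_group) >= 1,
              "case and control groups must be non-empty")
  if (length(intersect(case_group, control_group)) > 0) {
    cx_stop("case and control groups overlap in comparison ", sQuote(name))
  }
  structure(
    list(name = name, case_group = case_group, control_group = control_group),
    class = "Comparison"
  )
}

## Two-level factor (control first) for the samples entering a comparison,
## NA for samples in neither arm.
comparison_labels <- function(ds, cmp) {
  g <- ds$sample_groups
  lab <- rep(NA_character_, length(g))
  lab[g %in% cmp$control_group] <- "control"
  lab[g %in% cmp$case_group] <- "case"
  factor(lab, levels = c("control", "case"))
}

#' The five disease-stage comparisons
#'
#' Standard set of two-group contrasts along prostate-cancer development
#' and progression: tumor vs control, HGPIN vs control, tumor vs HGPIN,
#' metastatic-primary vs tumor, metastasis vs tumor.  Assumes control
#' groups have been merged (see [merge_control_groups()]).
#'
#' @return named list of [comparison()] objects.
#' @export
stage_comparisons <- function() {
  list(
    tumor_vs_normal = comparison("tumor_vs_normal", "primary_tumor", "control"),
    hgpin_vs_normal = comparison("hgpin_vs_normal", "HGPIN", "control"),
    tumor_vs_hgpin = comparison("tumor_vs_hgpin", "primary_tumor", "HGPIN"),
    met_primary_vs_tumor = comparison(
      "met_primary_vs_tumor", "metastatic_primary_tumor", "primary_tumor"),
    metastasis_vs_tumor = comparison(
      "metastasis_vs_tumor", "metastasis", "primary_tumor")
  )
}
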