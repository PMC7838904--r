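## Fixed TSV dialect everywhere: tab delimiter, "." decimal, UTF-8,
## first matrix column named "feature_id".  Keeps fixtures bit-stable.

read_tsv_file <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE, comment.char = "",
                    fileEncoding = "UTF-8")
}

write_tsv_file <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Load an expression dataset from a matrix TSV and a metadata TSV
#'
#' The matrix TSV carries feature ids in a first column named
#' `feature_id` and one column per sample.  The metadata TSV has one row
#' per sample with columns `sample`, `dataset`, `platform`, `group` and
#' optionally `tumor_content` and `feature_level`.  Samples present in the
#' matrix but missing from the metadata are an error; metadata rows with
#' no matching matrix column are dropped with a warning.  Sample order is
#' canonicalized to metadata order.
#'
#' @param matrix_path,metadata_path TSV file paths.
#' @return an [expression_dataset()].
#' @seealso [write_dataset()]
#' @export
load_dataset <- function(matrix_path, metadata_path) {
  mat_df <- read_tsv_file(matrix_path)
  assert_that(ncol(mat_df) >= 2, "matrix TSV needs feature_id plus >= 1 sample")
  if (names(mat_df)[1] != "feature_id") {
    cx_stop("first matrix column must be named 'feature_id', got ",
            sQuote(names(mat_df)[1]))
  }
  meta <- read_tsv_file(metadata_path)
  need <- c("sample", "dataset", "platform", "group")
  miss <- setdiff(need, names(meta))
  if (length(miss) > 0) {
    cx_stop("metadata missing column(s): ", paste(miss, collapse = ", "))
  }
  assert_that(!anyDuplicated(meta$sample), "duplicate sample ids in metadata")

  values <- as.matrix(mat_df[, -1, drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- as.character(mat_df$feature_id)

  extra_meta <- setdiff(meta$sample, colnames(values))
  if (length(extra_meta) > 0) {
    warning("dropping ", length(extra_meta),
            " metadata row(s) without matrix columns: ",
            paste(utils::head(extra_meta, 5), collapse = ", "))
    meta <- meta[!meta$sample %in% extra_meta, , drop = FALSE]
  }
  orphan <- setdiff(colnames(values), meta$sample)
  if (length(orphan) > 0) {
    cx_stop("matrix sample(s) absent from metadata: ",
            paste(utils::head(orphan, 5), collapse = ", "))
  }
  values <- values[, meta$sample, drop = FALSE]

  tc <- if ("tumor_content" %in% names(meta)) as.numeric(meta$tumor_content) else NULL
  lev <- if ("feature_level" %in% names(meta)) meta$feature_level[1] else "gene"
  expression_dataset(
    values,
    dataset_id = meta$dataset[1],
    platform_id = meta$platform[1],
    sample_groups = meta$group,
    tumor_content = tc,
    feature_level = lev
  )
}

#' Write an expression dataset as matrix + metadata TSVs
#'
#' Values are serialized with full double precision (17 significant
#' digits) so a write/load round trip preserves them to better than 1e-9
#' relative tolerance.
#'
#' @param ds an [expression_dataset()].
#' @param matrix_path,metadata_path output TSV file paths.
#' @return invisibly, the matrix path.
#' @export
write_dataset <- function(ds, matrix_path, metadata_path) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  df <- data.frame(feature_id = rownames(ds$values),
                   signif(ds$values, 17), check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv_file(df, matrix_path)
  meta <- data.frame(
    sample = colnames(ds$values),
    dataset = ds$dataset_id,
    platform = ds$platform_id,
    group = unname(ds$sample_groups),
    feature_level = ds$feature_level,
    stringsAsFactors = FALSE
  )
  if (!is.null(ds$tumor_content)) meta$tumor_content <- unname(ds$tumor_content)
  write_tsv_file(meta, metadata_path)
  invisible(matrix_path)
}

#' Read a plain-text gene list
#'
#' One gene symbol per line; blank lines and lines starting with `#` are
#' ignored; duplicates are collapsed.
#'
#' @param path file path.
#' @return character vector of gene ids.
#' @export
read_gene_list <- function(path) {
  x <- readLines(path, encoding = "UTF-8", warn = FALSE)
  x <- trimws(x)
  x <- x[nzchar(x) & !startsWith(x, "#")]
  unique(x)
}

#' Read a probe-to-gene map
#'
#' TSV with columns `probe_id` and `gene_id`.  Many probes may map to one
#' gene, but a probe mapping to more than one gene (insufficient
#' specificity) is an error: ambiguous probes must be removed upstream.
#'
#' @param path TSV file path.
#' @return data.frame with columns `probe_id`, `gene_id`.
#' @export
read_probe_map <- function(path) {
  df <- read_tsv_file(path)
  miss <- setdiff(c("probe_id", "gene_id"), names(df))
  if (length(miss) > 0) cx_stop("probe map missing column(s): ",
                                paste(miss, collapse = ", "))
  df <- unique(df[, c("probe_id", "gene_id")])
  dup <- df$probe_id[duplicated(df$probe_id)]
  if (length(dup) > 0) {
    cx_stop("probe(s) mapping to multiple genes: ",
            paste(utils::head(unique(dup), 5), collapse = ", "))
  }
  df
}

#' Read / write a survival table
#'
#' TSV with columns `sample_id`, `time` (non-negative, months) and
#' `event` (1 = biochemical recurrence observed, 0 = censored).
#'
#' @param path TSV file path.
#' @return data.frame with validated columns.
#' @export
read_survival_table <- function(path) {
  df <- read_tsv_file(path)
  miss <- setdiff(c("sample_id", "time", "event"), names(df))
  if (length(miss) > 0) cx_stop("survival table missing column(s): ",
                                paste(miss, collapse = ", "))
  validate_survival_table(df)
}

#' @rdname read_survival_table
#' @param surv data.frame with `sample_id`, `time`, `event`.
#' @export
write_survival_table <- function(surv, path) {
  write_tsv_file(validate_survival_table(surv), path)
}

validate_survival_table <- function(df) {
  assert_that(!anyDuplicated(df$sample_id), "duplicate sample_ids in survival table")
  assert_that(all(df$time >= 0), "survival times must be non-negative")
  assert_that(all(df$event %in% c(0, 1)), "event must be 0 or 1")
  df[, c("sample_id", "time", "event")]
}
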