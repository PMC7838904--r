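options(crossexpr.verbose = FALSE)

## Random gene x sample matrix with ids
rand_mat <- function(n_genes, n_samples, sd = 1, mean = 0, prefix = "g") {
  matrix(rnorm(n_genes * n_samples, mean, sd), n_genes, n_samples,
         dimnames = list(sprintf("%s%03d", prefix, seq_len(n_genes)),
                         sprintf("s%03d", seq_len(n_samples))))
}

## Small ExpressionDataset
make_ds <- function(n_genes = 10, groups = c("normal", "normal",
                                             "primary_tumor", "primary_tumor"),
                    dataset_id = "dsA", platform_id = "platA",
                    tumor_content = NULL, values = NULL) {
  v <- values %||% rand_mat(n_genes, length(groups))
  expression_dataset(v, dataset_id, platform_id, groups,
                     tumor_content = tumor_content)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Minimal DEResult for integration tests
make_de <- function(genes, log2fc, p, platform_id = "pl1",
                    comparison = "cmp") {
  d <- data.frame(gene = genes, log2fc = log2fc, t = 0, df = 10,
                  p = p, q = p, stringsAsFactors = FALSE)
  attr(d, "platform_id") <- platform_id
  attr(d, "comparison") <- comparison
  class(d) <- c("DEResult", "data.frame")
  d
}

## ICC table with prescribed per-platform values for a single gene set
make_icc <- function(genes, platform_values) {
  m <- do.call(cbind, platform_values)
  rownames(m) <- genes
  structure(list(pairs = NULL, per_platform = m,
                 icc = setNames(rowMeans(m), genes)),
            class = "ICCTable")
}

## Area under the ROC curve of `score` against a logical truth vector
auroc <- function(score, truth) {
  r <- rank(score)
  (sum(r[truth]) - sum(truth) * (sum(truth) + 1) / 2) /
    (sum(truth) * sum(!truth))
}
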