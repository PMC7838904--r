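#' Default molecular-alteration-map region specification
#'
#' A reconstruction of the natural reading of stage regions as overlaps
#' of the five stage comparisons' top-k gene sets (it is shipped data,
#' not a printed ground truth; supply your own spec to change it).
#' Each region lists the comparisons a gene must belong to
#' (`required_in`, comma separated) and those it must not
#' (`required_out`); comparisons left unmentioned are unconstrained.
#'
#' @return data.frame with columns `region`, `required_in`,
#'   `required_out`.
#' @export
default_region_spec <- function() {
  data.frame(
    region = c(
      "tumor_initiation_vs_normal_only",
      "tumor_hallmark_shared",
      "hgpin_initiation",
      "hgpin_transition_only",
      "progression_shared",
      "met_primary_specific",
      "metastasis_specific",
      "full_progression"
    ),
    required_in = c(
      "tumor_vs_normal",
      "tumor_vs_normal,tumor_vs_hgpin",
      "hgpin_vs_normal",
      "tumor_vs_hgpin",
      "met_primary_vs_tumor,metastasis_vs_tumor",
      "met_primary_vs_tumor",
      "metastasis_vs_tumor",
      "tumor_vs_normal,metastasis_vs_tumor"
    ),
    required_out = c(
      "tumor_vs_hgpin,hgpin_vs_normal",
      "",
      "tumor_vs_normal",
      "tumor_vs_normal",
      "",
      "metastasis_vs_tumor",
      "met_primary_vs_tumor",
      ""
    ),
    stringsAsFactors = FALSE
  )
}

split_spec_field <- function(x) {
  if (is.na(x) || !nzchar(x)) character(0) else trimws(strsplit(x, ",")[[1]])
}

#' Assemble the molecular alteration map
#'
#' Takes the top-k genes of every stage comparison and assigns each gene
#' in their union to every region whose membership pattern it satisfies
#' (member of all `required_in` comparisons' top-k sets, of none of the
#' `required_out` ones).  Genes matching no region land in an
#' `unassigned` bin, so the region system plus the bin closes a cover of
#' the union.  Direction per member comparison is the sign of the
#' combined Z.  Deterministic and invariant to input order.
#'
#' @param results named list of `IntegrationResult` objects, one per
#'   comparison (names = comparison names used by the region spec).
#' @param k top-list size (e.g. from [select_top_k()]); must not exceed
#'   any comparison's gene count.
#' @param region_spec region pattern table, default
#'   [default_region_spec()] restricted to the supplied comparisons.
#' @return a `MolecularAlterationMap` list: `assignments` (data.frame
#'   gene / region / comparison / direction), `counts` (per region:
#'   genes, up/down per comparison), `k`, `comparisons`.
#' @export
assemble_mam <- function(results, k, region_spec = NULL) {
  assert_that(is.list(results) && length(results) >= 1, "need >= 1 result")
  assert_that(!is.null(names(results)), "results must be named by comparison")
  results <- results[order(names(results))]
  comparisons <- names(results)
  if (is.null(region_spec)) {
    region_spec <- default_region_spec()
    ## keep regions whose required memberships are observable; exclusions
    ## referencing absent comparisons are vacuously satisfied
    keep <- vapply(seq_len(nrow(region_spec)), function(i) {
      all(split_spec_field(region_spec$required_in[i]) %in% comparisons)
    }, logical(1))
    region_spec <- region_spec[keep, , drop = FALSE]
    region_spec$required_out <- vapply(region_spec$required_out, function(x) {
      paste(intersect(split_spec_field(x), comparisons), collapse = ",")
    }, character(1), USE.NAMES = FALSE)
    region_spec <- region_spec[!duplicated(
      paste(region_spec$required_in, region_spec$required_out)), , drop = FALSE]
  }
  pat_key <- paste(region_spec$required_in, region_spec$required_out, sep = " || ")
  if (anyDuplicated(pat_key)) {
    cx_stop("contradictory region_spec: same pattern mapped to multiple regions")
  }
  for (cmp in comparisons) {
    if (k > nrow(results[[cmp]])) {
      cx_stop("k = ", k, " exceeds gene count of comparison ", sQuote(cmp))
    }
  }

  top_sets <- lapply(results, function(r) r$gene[r$rank <= k])
  direction <- lapply(results, function(r) {
    stats::setNames(ifelse(r$z_combined >= 0, "up", "down"), r$gene)
  })
  union_genes <- sort(unique(unlist(top_sets)))

  if (length(union_genes) == 0) {
    empty <- data.frame(gene = character(0), region = character(0),
                        comparison = character(0), direction = character(0),
                        stringsAsFactors = FALSE)
    return(structure(list(assignments = empty,
                          counts = data.frame(region = character(0),
                                              n_genes = integer(0)),
                          k = k, comparisons = comparisons),
                     class = "MolecularAlterationMap"))
  }

  membership <- vapply(top_sets, function(s) union_genes %in% s,
                       logical(length(union_genes)))
  membership <- matrix(membership, nrow = length(union_genes),
                       dimnames = list(union_genes, comparisons))

  rows <- list()
  matched <- rep(FALSE, length(union_genes))
  for (i in seq_len(nrow(region_spec))) {
    rin <- split_spec_field(region_spec$required_in[i])
    rout <- split_spec_field(region_spec$required_out[i])
    ok <- rep(TRUE, length(union_genes))
    for (cmp in rin) ok <- ok & membership[, cmp]
    for (cmp in rout) ok <- ok & !membership[, cmp]
    matched <- matched | ok
    g <- union_genes[ok]
    if (length(g) == 0) next
    member_cmps <- if (length(rin) > 0) rin else comparisons
    for (cmp in member_cmps) {
      in_cmp <- g[membership[g, cmp]]
      if (length(in_cmp) == 0) next
      rows[[length(rows) + 1]] <- data.frame(
        gene = in_cmp, region = region_spec$region[i], comparison = cmp,
        direction = unname(direction[[cmp]][in_cmp]), stringsAsFactors = FALSE
      )
    }
  }
  if (any(!matched)) {
    g <- union_genes[!matched]
    for (cmp in comparisons) {
      in_cmp <- g[membership[g, cmp]]
      if (length(in_cmp) == 0) next
      rows[[length(rows) + 1]] <- data.frame(
        gene = in_cmp, region = "unassigned", comparison = cmp,
        direction = unname(direction[[cmp]][in_cmp]), stringsAsFactors = FALSE
      )
    }
  }
  assignments <- do.call(rbind, rows)
  assignments <- assignments[order(assignments$region, assignments$gene,
                                   assignments$comparison), , drop = FALSE]
  rownames(assignments) <- NULL

  counts <- do.call(rbind, lapply(split(assignments, assignments$region),
    function(df) {
      data.frame(region = df$region[1],
                 n_genes = length(unique(df$gene)),
                 n_up = sum(df$direction == "up"),
                 n_down = sum(df$direction == "down"),
                 stringsAsFactors = FALSE)
    }))
  rownames(counts) <- NULL

  structure(list(assignments = assignments, counts = counts, k = k,
                 comparisons = comparisons),
            class = "MolecularAlterationMap")
}

#' @export
print.MolecularAlterationMap <- function(x, ...) {
  cat(sprintf("MolecularAlterationMap: top-%d sets over %d comparison(s)\n",
              x$k, length(x$comparisons)))
  print(x$counts)
  invisible(x)
}

#' Fisher-exact over-representation analysis
#'
#' One-sided (enrichment) Fisher exact test of a query gene set against
#' each annotation set, within a stated gene universe.  The p-value is
#' the hypergeometric upper tail of the overlap; the odds ratio is the
#' sample odds ratio of the 2x2 table (+Inf when the off-diagonal is
#' empty).  Results are BH-adjusted and sorted by p.
#'
#' @param genes character vector of query genes (subset of `universe`).
#' @param annotation_sets named list of character vectors; each is
#'   intersected with the universe before testing.
#' @param universe character vector of all assayable genes.
#' @return data.frame with columns `set`, `n_set`, `overlap`,
#'   `odds_ratio`, `p`, `q`, sorted by `p`.
#' @export
fisher_ora <- function(genes, annotation_sets, universe) {
  genes <- unique(genes)
  universe <- unique(universe)
  assert_that(length(genes) > 0, "empty query gene set")
  assert_that(length(universe) > 0, "empty universe")
  extra <- setdiff(genes, universe)
  if (length(extra) > 0) {
    cx_stop("query gene(s) outside the universe: ",
            paste(utils::head(extra, 5), collapse = ", "))
  }
  N <- length(universe)
  n <- length(genes)
  rows <- lapply(names(annotation_sets), function(nm) {
    set <- intersect(unique(annotation_sets[[nm]]), universe)
    K <- length(set)
    a <- length(intersect(genes, set))
    b <- n - a
    c <- K - a
    d <- N - n - c
    p <- stats::phyper(a - 1, K, N - K, n, lower.tail = FALSE)
    or <- if (b == 0 || c == 0) {
      if (a == 0) NA_real_ else Inf
    } else {
      (a * d) / (b * c)
    }
    data.frame(set = nm, n_set = K, overlap = a, odds_ratio = or, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out <- out[order(out$p, out$set), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then member genes, tab separated.
#'
#' @param path GMT file path.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t")[[1]]
    unique(f[-(1:2)])
  })
  names(sets) <- vapply(lines, function(l) strsplit(l, "\t")[[1]][1], character(1))
  sets
}
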