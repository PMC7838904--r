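#' Read a pipeline run configuration
#'
#' YAML (or JSON) file mirroring [run_pipeline()]'s expectations; every
#' analysis threshold is a config key with the standard value as default
#' (`tumor_content` 0.40, `top_k_default` 500, `fc_cut` 1.0, `alpha`
#' 0.05).
#'
#' @param path config file path.
#' @return named list.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  cfg$.config_path <- path
  cfg
}

default_thresholds <- function(th = NULL) {
  base <- list(tumor_content = 0.40, alpha = 0.05, top_k_default = 500,
               fc_cut = 1.0)
  if (!is.null(th)) base[names(th)] <- th
  base
}

stage_guard <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    cx_stop("pipeline stage '", stage, "' failed: ", conditionMessage(e))
  })
}

## Per-dataset log2FC table (case mean - control mean) for a comparison.
dataset_fc <- function(ds, cmp) {
  lab <- comparison_labels(ds, cmp)
  if (sum(lab == "case", na.rm = TRUE) < 2 ||
      sum(lab == "control", na.rm = TRUE) < 2) return(NULL)
  rowMeans(ds$values[, which(lab == "case"), drop = FALSE]) -
    rowMeans(ds$values[, which(lab == "control"), drop = FALSE])
}

#' Run the cross-platform integration pipeline end to end
#'
#' Stages mirror the integration workflow: (A) per-dataset
#' pre-processing (control-group merging, tumor-content filter, stromal
#' gene removal, probe collapsing, count transform); (B) per-platform
#' pooling with quantile normalization and empirical-Bayes batch
#' adjustment across datasets; (C) per-platform moderated-t differential
#' expression and integrative correlation per comparison; (D) ICC-weighted
#' Stouffer combination and ranking, then IDR curves, cross-dataset
#' concordance, top-k selection, molecular-alteration-map assembly, and
#' optional survival stratification.  Every intermediate table is written
#' to the run directory as TSV together with a JSON provenance manifest.
#'
#' @param config a config list or a path readable by [read_run_config()].
#'   Keys: `simulate` (generator settings; or `datasets`, a list of
#'   `matrix`/`metadata` path pairs), `stromal_lists` (gene-list paths),
#'   `probe_maps` (named per-platform TSV paths), `thresholds`,
#'   `comparisons` (names from [stage_comparisons()]; default all five),
#'   `survival` (`table` path, `genes`), `seed`, `out_dir`.
#' @param out_dir run directory (created); overrides the config key.
#' @param seed integer seed for the simulation stage; overrides config.
#' @return invisibly, a list with the run artifacts: `datasets`,
#'   `platform_data`, `de`, `integration`, `idr`, `concordance`, `k`,
#'   `mam`, `survival_fits`, `out_dir`.
#' @export
run_pipeline <- function(config, out_dir = NULL, seed = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  th <- default_thresholds(config$thresholds)
  seed <- seed %||% config$seed %||% 1L
  out_dir <- out_dir %||% config$out_dir %||% tempfile("crossexpr_run_")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  ## ---- Stage A: acquire and pre-process per-dataset ----
  datasets <- stage_guard("load", {
    if (!is.null(config$simulate)) {
      sim_cfg <- do.call(default_sim_config, as.list(config$simulate))
      sim <- generate_multiplatform(sim_cfg, seed = seed)
      truth_path <- file.path(out_dir, "synthetic_truth.json")
      jsonlite::write_json(
        list(seed = seed, de_union = sim$truth$de_union,
             de_genes = sim$truth$de_genes),
        truth_path, auto_unbox = TRUE)
      sim$datasets
    } else if (!is.null(config$datasets)) {
      ds <- lapply(config$datasets, function(d) {
        load_dataset(d$matrix, d$metadata)
      })
      stats::setNames(ds, vapply(ds, function(d) d$dataset_id, character(1)))
    } else {
      cx_stop("config needs either 'simulate' or 'datasets'")
    }
  })

  datasets <- stage_guard("preprocess", {
    lapply(datasets, function(ds) {
      ds <- merge_control_groups(ds)
      if (!is.null(ds$tumor_content)) {
        ds <- filter_by_tumor_content(ds, th$tumor_content)
      }
      if (!is.null(config$probe_maps) && ds$feature_level == "probe") {
        mp <- config$probe_maps[[ds$platform_id]]
        if (is.null(mp)) cx_stop("no probe map for platform ", ds$platform_id)
        ds <- collapse_probes_max_sd(ds, read_probe_map(mp))
      }
      if (identical(ds$data_type, "rnaseq") && !is.null(ds$counts)) {
        vt <- voom_transform(ds$counts, groups = NULL)
        ds$values <- vt$logcpm
        ds$weights <- vt$weights
      }
      if (!is.null(config$stromal_lists)) {
        ds <- remove_stromal_genes(ds, unlist(config$stromal_lists))
      }
      ds
    })
  })

  ## ---- Stage B: pool per platform, normalize, batch-adjust ----
  platforms <- unique(vapply(datasets, function(d) d$platform_id, character(1)))
  platform_data <- stage_guard("combine", {
    out <- list()
    for (p in platforms) {
      members <- Filter(function(d) d$platform_id == p, datasets)
      shared <- Reduce(intersect, lapply(members, function(d) rownames(d$values)))
      mat <- do.call(cbind, lapply(members, function(d) {
        d$values[shared, , drop = FALSE]
      }))
      batch <- unlist(lapply(members, function(d) rep(d$dataset_id, ncol(d$values))))
      grp <- unlist(lapply(members, function(d) unname(d$sample_groups)))
      mat <- quantile_normalize(mat)
      adj <- combat_adjust(mat, batch, covariates = grp, passthrough = TRUE)
      out[[p]] <- list(values = adj$adjusted, groups = grp, batch = batch,
                       datasets = members)
    }
    out
  })

  ## ---- Stage C/D: per-comparison DE, ICC, combination ----
  cmp_names <- config$comparisons %||% names(stage_comparisons())
  cmps <- stage_comparisons()[cmp_names]
  if (any(vapply(cmps, is.null, logical(1)))) {
    cx_stop("unknown comparison(s): ",
            paste(cmp_names[vapply(cmps, is.null, logical(1))], collapse = ", "))
  }

  integration <- list(); de_all <- list(); idr <- list(); concordance <- list()
  for (cmp in cmps) {
    de_list <- list(); icc_mats <- list(); fc_tables <- list()
    for (p in names(platform_data)) {
      pd <- platform_data[[p]]
      lab <- rep(NA_character_, length(pd$groups))
      lab[pd$groups %in% cmp$control_group] <- "control"
      lab[pd$groups %in% cmp$case_group] <- "case"
      lab <- factor(lab, levels = c("control", "case"))
      if (sum(lab == "case", na.rm = TRUE) < 2 ||
          sum(lab == "control", na.rm = TRUE) < 2) next
      de_list[[p]] <- moderated_t(pd$values, lab, platform_id = p,
                                  comparison = cmp$name)
      icc_mats[[p]] <- pd$values[, !is.na(lab), drop = FALSE]
      for (m in pd$datasets) {
        fc <- dataset_fc(m, cmp)
        if (!is.null(fc)) fc_tables[[m$dataset_id]] <- fc
      }
    }
    if (length(de_list) == 0) {
      cx_log("comparison ", cmp$name, ": no platform with both arms; skipped")
      next
    }
    icc <- if (length(icc_mats) >= 2) integrative_correlation(icc_mats) else NULL
    res <- stage_guard(paste0("integrate:", cmp$name),
                       combine_platforms(de_list, icc))
    integration[[cmp$name]] <- res
    de_all[[cmp$name]] <- de_list
    idr[[cmp$name]] <- idr_curve(res)
    involves_hgpin <- "HGPIN" %in% c(cmp$case_group, cmp$control_group)
    if (length(fc_tables) >= 2 && !involves_hgpin) {
      kmax <- min(2000, nrow(res))
      concordance[[cmp$name]] <- concordance_curve(
        res, fc_tables, k_grid = seq(50, kmax, by = 50), fc_cut = th$fc_cut)
    }
  }
  if (length(integration) == 0) cx_stop("no comparison could be evaluated")

  k <- if (length(concordance) >= 1) {
    select_top_k(concordance, default_k = th$top_k_default)
  } else {
    th$top_k_default
  }
  k <- min(k, min(vapply(integration, nrow, 0L)))
  mam <- stage_guard("mam", assemble_mam(integration, k))

  ## ---- optional survival stage ----
  survival_fits <- NULL
  if (!is.null(config$survival)) {
    survival_fits <- stage_guard("survival", {
      surv <- read_survival_table(config$survival$table)
      pd <- platform_data[[1]]
      lapply(stats::setNames(config$survival$genes, config$survival$genes),
             function(g) {
               best_cutoff_stratify(pd$values[g, ], surv, gene = g)
             })
    })
  }

  ## ---- persist artifacts ----
  for (nm in names(integration)) {
    write_tsv_file(as.data.frame(integration[[nm]]),
                   file.path(out_dir, paste0("integration_", nm, ".tsv")))
    write_tsv_file(idr[[nm]], file.path(out_dir, paste0("idr_", nm, ".tsv")))
    for (p in names(de_all[[nm]])) {
      write_tsv_file(as.data.frame(de_all[[nm]][[p]]),
                     file.path(out_dir, paste0("de_", nm, "_", p, ".tsv")))
    }
  }
  for (nm in names(concordance)) {
    write_tsv_file(concordance[[nm]],
                   file.path(out_dir, paste0("concordance_", nm, ".tsv")))
  }
  write_tsv_file(mam$assignments, file.path(out_dir, "mam_assignments.tsv"))
  write_tsv_file(mam$counts, file.path(out_dir, "mam_counts.tsv"))

  manifest <- list(
    package = "crossexpr",
    version = as.character(utils::packageVersion("crossexpr")),
    r_version = R.version.string,
    seed = seed,
    top_k = k,
    thresholds = th,
    comparisons = names(integration),
    config_md5 = if (!is.null(config$.config_path))
      unname(tools::md5sum(config$.config_path)) else NA,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  cx_log("run complete: ", out_dir, " (top-k = ", k, ")")

  invisible(list(datasets = datasets, platform_data = platform_data,
                 de = de_all, integration = integration, idr = idr,
                 concordance = concordance, k = k, mam = mam,
                 survival_fits = survival_fits, out_dir = out_dir))
}

#' Command-line entry point
#'
#' Thin wrapper used by the installed `exec/crossexpr` script.
#' Subcommands: `simulate` (write synthetic datasets as TSV pairs),
#' `run-all` (full pipeline from a config file).  Exit codes: 0 success,
#' 2 validation error, 3 runtime failure.
#'
#' @param args character vector, default `commandArgs(trailingOnly = TRUE)`.
#' @return exit status, invisibly.
#' @export
crossexpr_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: crossexpr <simulate|run-all> [options]",
    "  simulate --out DIR [--seed N] [--genes N] [--platforms N]",
    "  run-all  --config FILE [--out DIR] [--seed N]",
    sep = "\n")
  if (length(args) < 1) { message(usage); return(invisible(2L)) }
  cmd <- args[1]
  opt <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (length(i) == 1 && i < length(args)) args[i + 1] else default
  }
  status <- tryCatch({
    if (cmd == "simulate") {
      out <- opt("--out"); if (is.null(out)) cx_stop("simulate needs --out")
      dir.create(out, recursive = TRUE, showWarnings = FALSE)
      cfg <- default_sim_config(
        n_genes = as.integer(opt("--genes", "500")),
        n_platforms = as.integer(opt("--platforms", "2"))
      )
      sim <- generate_multiplatform(cfg, seed = as.integer(opt("--seed", "1")))
      for (ds in sim$datasets) {
        write_dataset(ds,
                      file.path(out, paste0(ds$dataset_id, "_matrix.tsv")),
                      file.path(out, paste0(ds$dataset_id, "_metadata.tsv")))
      }
      jsonlite::write_json(list(de_union = sim$truth$de_union,
                                seed = sim$truth$seed),
                           file.path(out, "truth.json"), auto_unbox = TRUE)
      0L
    } else if (cmd == "run-all") {
      cfgp <- opt("--config"); if (is.null(cfgp)) cx_stop("run-all needs --config")
      seed <- opt("--seed"); if (!is.null(seed)) seed <- as.integer(seed)
      run_pipeline(cfgp, out_dir = opt("--out"), seed = seed)
      0L
    } else {
      message(usage); 2L
    }
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    if (grepl("needs|unknown|config", conditionMessage(e))) 2L else 3L
  })
  invisible(status)
}
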