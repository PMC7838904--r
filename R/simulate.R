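#' Default settings for the multi-platform generator
#'
#' The stated world of the synthetic cohort collection: 5000 genes, 3
#' platforms with 2 datasets each, 15 samples per biological group, 4%
#' of genes differentially expressed per non-control group with
#' log-normal(0, 0.5) effect sizes and random sign, additive per-batch
#' gene-level shifts, multiplicative per-batch scale effects,
#' platform-specific 80% gene coverage, platform-heterogeneous noise, and
#' tumor/stroma admixture attenuating tumor effects by the sample's
#' tumor-content fraction.
#'
#' @param ... overrides for any setting.
#' @return config list.
#' @export
default_sim_config <- function(...) {
  cfg <- list(
    n_genes = 5000,
    n_platforms = 3,
    datasets_per_platform = 2,
    samples_per_group = 15,
    groups = c("control", "primary_tumor"),
    de_fraction = 0.04,
    effect_meanlog = 0,
    effect_sdlog = 0.5,
    baseline_mean = 7,
    baseline_sd = 1.5,
    batch_shift_sd = 0.5,       # SD of per-dataset shift centers
    batch_shift_gene_sd = 0.5,  # per-gene spread around the center
    batch_scale_sdlog = 0.3,    # log-normal per-gene scale effects
    coverage_fraction = 0.8,
    noise_sd_range = c(0.7, 1.3),
    tumor_content_shape = c(8, 3),  # Beta draw of tumor fractions
    admixture = TRUE,
    platform_types = NULL,      # default all "array"; set "rnaseq" per platform
    nb_dispersion = 0.1
  )
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Simulate multi-dataset, multi-platform expression with known truth
#'
#' Draws a gene universe once, assigns every platform a coverage subset
#' and noise level, plants group-specific differential expression, then
#' emits one dataset per platform/replicate with per-gene additive batch
#' shifts and multiplicative batch scale following the location/scale
#' model that empirical-Bayes batch adjustment assumes.  Tumor-bearing
#' samples get a tumor-content fraction, and (with `admixture = TRUE`)
#' their planted effects are attenuated proportionally.  Platforms marked
#' `"rnaseq"` additionally emit negative-binomial counts (mean
#' `2^gaussian_value`) in the dataset's `counts` field for testing the
#' count transform.  All randomness flows from `seed` through per-stage
#' sub-streams, so equal seeds give identical output.
#'
#' @param config settings list, see [default_sim_config()].
#' @param seed integer seed.
#' @return list with `datasets` (list of [expression_dataset()], each
#'   with a `data_type` field) and `truth` (a `SyntheticTruth` list:
#'   `group_effects` gene x group matrix, `de_genes` per non-control
#'   group and their union, per-dataset `batch` location/scale vectors,
#'   `coverage` per platform, `noise_sd` per platform, `tumor_content`
#'   per dataset, `seed`, `config`).
#' @export
generate_multiplatform <- function(config = default_sim_config(), seed = 1) {
  cfg <- config
  assert_that(cfg$n_genes >= 10, "need >= 10 genes")
  assert_that(cfg$coverage_fraction > 0, "coverage fraction must be positive")
  assert_that(length(cfg$groups) >= 2, "need >= 2 biological groups")
  n_datasets <- cfg$n_platforms * cfg$datasets_per_platform
  seeds <- derive_subseeds(seed, 2 + n_datasets)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)

  genes <- sprintf("g%05d", seq_len(cfg$n_genes))
  platform_types <- cfg$platform_types %||% rep("array", cfg$n_platforms)
  assert_that(length(platform_types) == cfg$n_platforms,
              "one platform type per platform")

  ## Stage 1: universe, baselines, planted effects
  set.seed(seeds[1])
  baseline <- stats::rnorm(cfg$n_genes, cfg$baseline_mean, cfg$baseline_sd)
  names(baseline) <- genes
  non_control <- setdiff(cfg$groups, "control")
  effects <- matrix(0, cfg$n_genes, length(cfg$groups),
                    dimnames = list(genes, cfg$groups))
  de_genes <- list()
  n_de <- round(cfg$de_fraction * cfg$n_genes)
  for (g in non_control) {
    idx <- sample.int(cfg$n_genes, n_de)
    mag <- stats::rlnorm(n_de, cfg$effect_meanlog, cfg$effect_sdlog)
    sgn <- sample(c(-1, 1), n_de, replace = TRUE)
    effects[idx, g] <- mag * sgn
    de_genes[[g]] <- genes[idx]
  }

  ## Stage 2: platform coverage and noise heterogeneity
  set.seed(seeds[2])
  coverage <- lapply(seq_len(cfg$n_platforms), function(p) {
    sort(sample(genes, round(cfg$coverage_fraction * cfg$n_genes)))
  })
  names(coverage) <- sprintf("platform%d", seq_len(cfg$n_platforms))
  noise_sd <- stats::runif(cfg$n_platforms, cfg$noise_sd_range[1],
                           cfg$noise_sd_range[2])

  ## Stage 3: one dataset per platform replicate
  datasets <- list()
  batch_truth <- list()
  tc_truth <- list()
  d <- 0L
  for (p in seq_len(cfg$n_platforms)) {
    for (rep_i in seq_len(cfg$datasets_per_platform)) {
      d <- d + 1L
      set.seed(seeds[2 + d])
      gset <- coverage[[p]]
      nG <- length(gset)
      ns <- cfg$samples_per_group * length(cfg$groups)
      grp <- rep(cfg$groups, each = cfg$samples_per_group)
      ds_id <- sprintf("ds%02d", d)
      sample_ids <- sprintf("%s_s%03d", ds_id, seq_len(ns))

      shift_center <- stats::rnorm(1, 0, cfg$batch_shift_sd)
      gamma <- stats::rnorm(nG, shift_center, cfg$batch_shift_gene_sd)
      delta <- stats::rlnorm(nG, 0, cfg$batch_scale_sdlog)
      names(gamma) <- names(delta) <- gset

      is_tumor <- grp %in% TUMOR_BEARING_GROUPS
      tc <- rep(NA_real_, ns)
      tc[is_tumor] <- stats::rbeta(sum(is_tumor), cfg$tumor_content_shape[1],
                                   cfg$tumor_content_shape[2])
      admix <- rep(1, ns)
      if (isTRUE(cfg$admixture)) admix[is_tumor] <- tc[is_tumor]

      eff <- effects[gset, grp, drop = FALSE] *
        matrix(admix, nG, ns, byrow = TRUE)
      eps <- matrix(stats::rnorm(nG * ns, 0, noise_sd[p]), nG, ns)
      x <- baseline[gset] + eff + gamma + delta * eps
      dimnames(x) <- list(gset, sample_ids)

      ds <- expression_dataset(x, ds_id, names(coverage)[p], grp,
                               tumor_content = tc, feature_level = "gene")
      ds$data_type <- platform_types[p]
      if (platform_types[p] == "rnaseq") {
        mu <- pmax(2^x, 1e-8)
        cnt <- matrix(
          stats::rnbinom(nG * ns, mu = as.vector(mu), size = 1 / cfg$nb_dispersion),
          nG, ns, dimnames = dimnames(x)
        )
        ds$counts <- cnt
      }
      datasets[[ds_id]] <- ds
      batch_truth[[ds_id]] <- list(gamma = gamma, delta = delta,
                                   shift_center = shift_center)
      tc_truth[[ds_id]] <- stats::setNames(tc, sample_ids)
    }
  }

  truth <- structure(list(
    group_effects = effects,
    de_genes = de_genes,
    de_union = sort(unique(unlist(de_genes))),
    batch = batch_truth,
    coverage = coverage,
    noise_sd = stats::setNames(noise_sd, names(coverage)),
    tumor_content = tc_truth,
    platform_types = stats::setNames(platform_types, names(coverage)),
    seed = seed,
    config = cfg
  ), class = "SyntheticTruth")

  list(datasets = datasets, truth = truth)
}

#' Simulate survival linked to expression through a planted cutpoint
#'
#' Exponential event times whose hazard is multiplied by `true_hr` for
#' samples whose expression exceeds the planted cutpoint (default the
#' observed median).  Independent uniform censoring is calibrated so that
#' approximately `censoring_rate` of samples are censored;
#' `censoring_rate = 0` observes every event.
#'
#' @param expr named numeric vector of per-sample expression.
#' @param true_hr hazard ratio above vs below the cutpoint (> 0).
#' @param censoring_rate target censored fraction in \[0, 1).
#' @param seed integer seed.
#' @param cutpoint expression cutpoint; default `median(expr)`.
#' @param base_rate baseline hazard (events per month), default 0.02.
#' @return survival table data.frame (`sample_id`, `time`, `event`) with
#'   attributes `true_hr` and `cutpoint`.
#' @export
generate_survival <- function(expr, true_hr, censoring_rate = 0.2, seed = 1,
                              cutpoint = NULL, base_rate = 0.02) {
  assert_that(true_hr > 0, "true_hr must be positive")
  assert_that(censoring_rate >= 0 && censoring_rate < 1,
              "censoring_rate must lie in [0, 1)")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  if (is.null(cutpoint)) cutpoint <- stats::median(expr)
  high <- expr > cutpoint
  rate <- base_rate * ifelse(high, true_hr, 1)
  t_event <- stats::rexp(length(expr), rate = rate)

  if (censoring_rate == 0) {
    time <- t_event
    event <- rep(1, length(expr))
  } else {
    ## P(censored | uniform(0, cmax) censoring) for an Exp(r) time is
    ## (1 - exp(-r * cmax)) / (r * cmax); average over the two hazards
    ## and solve for cmax.
    cens_frac <- function(cmax) {
      mean((1 - exp(-rate * cmax)) / (rate * cmax))
    }
    cmax <- stats::uniroot(function(cm) cens_frac(cm) - censoring_rate,
                           lower = 1e-6, upper = 1e8, tol = 1e-9)$root
    t_cens <- stats::runif(length(expr), 0, cmax)
    event <- as.numeric(t_event <= t_cens)
    time <- pmin(t_event, t_cens)
  }
  out <- data.frame(
    sample_id = names(expr) %||% sprintf("s%04d", seq_along(expr)),
    time = time, event = event, stringsAsFactors = FALSE
  )
  attr(out, "true_hr") <- true_hr
  attr(out, "cutpoint") <- cutpoint
  out
}
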