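small_cfg <- function(...) {
  default_sim_config(n_genes = 120, n_platforms = 2, datasets_per_platform = 1,
                     samples_per_group = 6, ...)
}

test_that("the generator is deterministic in the seed", {
  s1 <- generate_multiplatform(small_cfg(), seed = 7)
  s2 <- generate_multiplatform(small_cfg(), seed = 7)
  expect_identical(s1, s2)
  s3 <- generate_multiplatform(small_cfg(), seed = 8)
  expect_false(identical(s1$datasets[[1]]$values, s3$datasets[[1]]$values))
  # seed recorded in the truth
  expect_identical(s1$truth$seed, 7)
})

test_that("generator respects its config contract", {
  cfg <- small_cfg(coverage_fraction = 0.5,
                   groups = c("control", "primary_tumor", "metastasis"))
  sim <- generate_multiplatform(cfg, seed = 9)
  expect_length(sim$datasets, 2)
  for (ds in sim$datasets) {
    expect_equal(nrow(ds$values), 60)  # 50% coverage of 120 genes
    expect_equal(ncol(ds$values), 18)  # 6 per group, 3 groups
    expect_true(all(rownames(ds$values) %in% sprintf("g%05d", 1:120)))
    tc <- ds$tumor_content
    tumor <- ds$sample_groups %in%
      c("primary_tumor", "metastatic_primary_tumor", "metastasis")
    expect_true(all(!is.na(tc[tumor])))
    expect_true(all(is.na(tc[!tumor])))
  }
  # coverage lists are subsets of the universe and recorded
  expect_true(all(unlist(sim$truth$coverage) %in% sprintf("g%05d", 1:120)))
  expect_error(generate_multiplatform(small_cfg(coverage_fraction = 0)),
               "coverage")
})

test_that("null generation is calibrated at the nominal t-test level", {
  set.seed(91)
  pvals <- unlist(lapply(1:100, function(i) {
    sim <- generate_multiplatform(
      default_sim_config(n_genes = 100, n_platforms = 1,
                         datasets_per_platform = 1, samples_per_group = 5,
                         de_fraction = 0, batch_shift_sd = 0,
                         batch_shift_gene_sd = 0, batch_scale_sdlog = 0,
                         noise_sd_range = c(1, 1), admixture = FALSE),
      seed = 9000 + i)
    v <- sim$datasets[[1]]$values
    grp <- sim$datasets[[1]]$sample_groups
    apply(v, 1, function(r) {
      t.test(r[grp == "primary_tumor"], r[grp == "control"],
             var.equal = TRUE)$p.value
    })
  }))
  frac <- mean(pvals < 0.05)
  se <- sqrt(0.05 * 0.95 / length(pvals))
  # 3-SE band: the t-test is exact here, so any excursion is Monte-Carlo
  # noise and a 2-SE band would fail one run in twenty by construction
  expect_lt(abs(frac - 0.05), 3 * se)
  # p-values are uniform well beyond the 5% tail
  expect_lt(abs(mean(pvals < 0.25) - 0.25), 3 * sqrt(0.25 * 0.75 / length(pvals)))
})

test_that("planted effects appear at their stated size", {
  diffs <- vapply(1:100, function(i) {
    sim <- generate_multiplatform(
      default_sim_config(n_genes = 30, n_platforms = 1,
                         datasets_per_platform = 1, samples_per_group = 20,
                         de_fraction = 0, batch_shift_sd = 0,
                         batch_shift_gene_sd = 0, batch_scale_sdlog = 0,
                         noise_sd_range = c(1, 1), admixture = FALSE),
      seed = 500 + i)
    ds <- sim$datasets[[1]]
    v <- ds$values
    grp <- ds$sample_groups
    mean(v[1, grp == "primary_tumor"]) - mean(v[1, grp == "control"])
  }, numeric(1))
  # null gene: mean difference ~ N(0, 2/20 / 100)
  expect_lt(abs(mean(diffs)), 3 * sqrt(2 / 20 / 100))

  # now with a planted effect: group difference matches effect * mean admix
  sim <- generate_multiplatform(
    default_sim_config(n_genes = 200, n_platforms = 1,
                       datasets_per_platform = 1, samples_per_group = 20,
                       de_fraction = 0.5, batch_shift_sd = 0,
                       batch_shift_gene_sd = 0, batch_scale_sdlog = 0,
                       noise_sd_range = c(1, 1), admixture = FALSE),
    seed = 77)
  ds <- sim$datasets[[1]]
  eff <- sim$truth$group_effects[rownames(ds$values), "primary_tumor"]
  grp <- ds$sample_groups
  obs <- rowMeans(ds$values[, grp == "primary_tumor"]) -
    rowMeans(ds$values[, grp == "control"])
  se <- sqrt(2 / 20)
  planted <- eff != 0
  expect_lt(mean(abs(obs[planted] - eff[planted])), 3 * se)
  expect_gt(cor(obs[planted], eff[planted]), 0.9)
})

test_that("tumor/stroma admixture attenuates planted effects", {
  cfg <- default_sim_config(n_genes = 300, n_platforms = 1,
                            datasets_per_platform = 1, samples_per_group = 25,
                            de_fraction = 0.3, batch_shift_sd = 0,
                            batch_shift_gene_sd = 0, batch_scale_sdlog = 0,
                            noise_sd_range = c(1, 1),
                            tumor_content_shape = c(2, 4))  # low purity
  sim_mix <- generate_multiplatform(cfg, seed = 13)
  cfg$admixture <- FALSE
  sim_pure <- generate_multiplatform(cfg, seed = 13)
  grp <- sim_mix$datasets[[1]]$sample_groups
  eff <- sim_mix$truth$group_effects[, "primary_tumor"]
  planted <- names(eff)[eff != 0]
  planted <- intersect(planted, rownames(sim_mix$datasets[[1]]$values))
  obs_mix <- rowMeans(sim_mix$datasets[[1]]$values[planted, grp == "primary_tumor"]) -
    rowMeans(sim_mix$datasets[[1]]$values[planted, grp == "control"])
  obs_pure <- rowMeans(sim_pure$datasets[[1]]$values[planted, grp == "primary_tumor"]) -
    rowMeans(sim_pure$datasets[[1]]$values[planted, grp == "control"])
  # attenuation toward zero by roughly the mean tumor content (1/3)
  fit <- lm(obs_mix ~ 0 + obs_pure)
  expect_lt(unname(coef(fit)), 0.6)
  expect_gt(unname(coef(fit)), 0.15)
})

test_that("rnaseq platforms emit negative-binomial counts", {
  cfg <- small_cfg(platform_types = c("array", "rnaseq"), baseline_mean = 5)
  sim <- generate_multiplatform(cfg, seed = 10)
  rnaseq <- Filter(function(d) identical(d$data_type, "rnaseq"), sim$datasets)
  expect_length(rnaseq, 1)
  cnt <- rnaseq[[1]]$counts
  expect_true(all(cnt >= 0) && all(cnt == round(cnt)))
  # counts feed the voom transform
  vt <- voom_transform(cnt)
  expect_true(all(vt$weights > 0))
})

test_that("batch parameters are recovered by the EB adjustment", {
  sim <- generate_multiplatform(default_sim_config(n_genes = 2000), seed = 15)
  ds <- Filter(function(d) d$platform_id == "platform1", sim$datasets)
  shared <- Reduce(intersect, lapply(ds, function(d) rownames(d$values)))
  mat <- do.call(cbind, lapply(ds, function(d) d$values[shared, ]))
  batch <- unlist(lapply(ds, function(d) rep(d$dataset_id, ncol(d$values))))
  grp <- unlist(lapply(ds, function(d) unname(d$sample_groups)))
  out <- combat_adjust(mat, batch, covariates = grp)
  est_gamma <- (out$model$gamma_star[, 2] - out$model$gamma_star[, 1]) *
    sqrt(out$model$var_pooled)
  true_gamma <- sim$truth$batch[[names(ds)[2]]]$gamma[shared] -
    sim$truth$batch[[names(ds)[1]]]$gamma[shared]
  # statistical ceiling of the design: signal SD of the planted location
  # difference against the standard error of a 30-vs-30-sample mean
  # difference; recovery must reach 95% of that attenuation ceiling
  cfg <- sim$truth$config
  sd_signal <- sqrt(2) * cfg$batch_shift_gene_sd
  mean_noise_var <- exp(2 * cfg$batch_scale_sdlog^2) *
    mean(sim$truth$noise_sd^2)
  n_per_batch <- cfg$samples_per_group * length(cfg$groups)
  se_est <- sqrt(2 * mean_noise_var / n_per_batch)
  ceiling_cor <- sd_signal / sqrt(sd_signal^2 + se_est^2)
  expect_gt(cor(est_gamma, true_gamma), 0.95 * ceiling_cor)
  expect_gt(cor(est_gamma, true_gamma), 0.85)
  # scale effects: estimated delta2 ratio tracks the planted delta ratio
  est_scale <- log(out$model$delta2_hat[, 2] / out$model$delta2_hat[, 1])
  true_scale <- 2 * log(sim$truth$batch[[names(ds)[2]]]$delta[shared] /
                          sim$truth$batch[[names(ds)[1]]]$delta[shared])
  expect_gt(cor(est_scale, true_scale), 0.9)
})

test_that("generated survival honors the censoring contract", {
  expr <- setNames(rnorm(400), sprintf("s%03d", 1:400))
  s0 <- generate_survival(expr, true_hr = 2, censoring_rate = 0, seed = 3)
  expect_true(all(s0$event == 1))
  s1 <- generate_survival(expr, true_hr = 2, censoring_rate = 0.3, seed = 3)
  expect_lt(abs(mean(s1$event == 0) - 0.3), 0.08)
  expect_identical(s1, generate_survival(expr, 2, 0.3, seed = 3))
  expect_error(generate_survival(expr, -1, 0.2), "positive")
  # the planted hazard ratio is detectable
  fit <- cox_univariate(s1$time, s1$event,
                        factor(ifelse(expr > attr(s1, "cutpoint"),
                                      "high", "low"),
                               levels = c("low", "high")))
  expect_gt(fit$hr, 1.4)
})
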