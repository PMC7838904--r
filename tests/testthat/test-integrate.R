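test_that("ICC identities: exact copy and negated gene", {
  set.seed(61)
  A <- rand_mat(50, 12)
  # an exact copy gives ICC 1 everywhere
  icc <- integrative_correlation(list(p1 = A, p2 = A))
  expect_true(all(abs(icc$icc - 1) < 1e-10))

  # negating one gene flips its ICC to -1; the other genes' correlation
  # profiles change in that single coordinate, so they drop slightly
  # below 1 — verified against the double-loop oracle, not assumed
  B <- A; B["g005", ] <- -A["g005", ]
  icc2 <- integrative_correlation(list(p1 = A, p2 = B))
  expect_equal(unname(icc2$icc["g005"]), -1, tolerance = 1e-10)
  others <- setdiff(rownames(A), "g005")
  oracle <- sapply(others, function(g) {
    rest <- setdiff(rownames(A), g)
    cor(sapply(rest, function(h) cor(A[g, ], A[h, ])),
        sapply(rest, function(h) cor(B[g, ], B[h, ])))
  })
  expect_equal(unname(icc2$icc[others]), unname(oracle), tolerance = 1e-10)
  expect_true(all(icc2$icc[others] > 0.6 & icc2$icc[others] < 1))
  expect_gt(mean(icc2$icc[others]), 0.9)
})

test_that("ICC matches the brute-force double-loop oracle", {
  set.seed(62)
  A <- rand_mat(4, 6); B <- rand_mat(4, 6)
  icc <- integrative_correlation(list(pA = A, pB = B))
  oracle <- sapply(rownames(A), function(g) {
    others <- setdiff(rownames(A), g)
    vA <- sapply(others, function(h) cor(A[g, ], A[h, ]))
    vB <- sapply(others, function(h) cor(B[g, ], B[h, ]))
    cor(vA, vB)
  })
  expect_equal(unname(icc$icc[names(oracle)]), unname(oracle),
               tolerance = 1e-10)
  expect_true(all(icc$pairs$r >= -1 & icc$pairs$r <= 1))
})

test_that("ICC of independent platforms concentrates near zero", {
  ## Null ceiling: profile correlations over m - 1 coordinates behave like
  ## iid normal correlations, E|ICC| ~ sqrt(2 / (pi (m - 1)))  (0.114 at
  ## m = 50) — so the bound scales with the shared-universe size
  set.seed(63)
  null_mean_abs <- function(m, reps) {
    mean(replicate(reps, {
      A <- rand_mat(m, 20); B <- rand_mat(m, 20)
      mean(abs(integrative_correlation(list(a = A, b = B))$icc))
    }))
  }
  v50 <- null_mean_abs(50, 40)
  expect_lt(v50, 1.5 * sqrt(2 / (pi * 49)))
  v200 <- null_mean_abs(200, 10)
  expect_lt(v200, 1.5 * sqrt(2 / (pi * 199)))
  expect_lt(v200, v50)  # concentration with a larger shared universe
})

test_that("zero-variance genes get ICC 0 and three platforms average pairs", {
  set.seed(64)
  A <- rand_mat(10, 8); B <- rand_mat(10, 8); C <- rand_mat(10, 8)
  A["g003", ] <- 7  # flat gene
  icc <- integrative_correlation(list(a = A, b = B, c = C))
  pr <- icc$pairs[icc$pairs$gene == "g003" & icc$pairs$platform_a == "a", ]
  expect_true(all(pr$r == 0))
  g1 <- icc$pairs$r[icc$pairs$gene == "g001"]
  expect_equal(unname(icc$icc["g001"]), mean(g1), tolerance = 1e-12)
  # per-platform summary averages the pairs involving that platform
  g1a <- icc$pairs[icc$pairs$gene == "g001" &
                     (icc$pairs$platform_a == "a" | icc$pairs$platform_b == "a"), ]
  expect_equal(unname(icc$per_platform["g001", "a"]), mean(g1a$r),
               tolerance = 1e-12)
})

test_that("the Stouffer weight follows W = |fc| (1 + ICC^2)", {
  expect_equal(stouffer_weight(1, 1), 2)
  expect_equal(stouffer_weight(0, 0.7), 0)
  expect_equal(stouffer_weight(-2, 0.5), 2.5)
  expect_error(stouffer_weight(1, 1.5), "-1, 1")
  # range property over random draws
  set.seed(65)
  fc <- rnorm(100); ic <- runif(100, -1, 1)
  w <- stouffer_weight(fc, ic)
  expect_true(all(w >= abs(fc) - 1e-12 & w <= 2 * abs(fc) + 1e-12))
})

test_that("combination limits: single platform and equal weights", {
  d1 <- make_de(c("a", "b", "c"), c(1.2, -0.8, 0.5), c(0.01, 0.20, 0.70))
  res1 <- combine_platforms(list(pl1 = d1), icc = NULL)
  expect_equal(res1$p_combined[match(c("a", "b", "c"), res1$gene)],
               d1$p, tolerance = 1e-12)
  expect_equal(sign(res1$z_combined[match(c("a", "b"), res1$gene)]),
               c(1, -1))

  # equal weights, both platform Z equal to z -> combined = z * sqrt(2)
  d2 <- make_de("a", 1.2, 0.01, platform_id = "pl2")
  res2 <- combine_platforms(list(pl1 = make_de("a", 1.2, 0.01), pl2 = d2),
                            icc = NULL)
  z <- qnorm(1 - 0.01 / 2)
  expect_equal(res2$z_combined, z * sqrt(2), tolerance = 1e-12)

  # equal weights on many genes reduce to the textbook Stouffer statistic
  set.seed(66)
  p1 <- runif(20); p2 <- runif(20); fc <- rep(1, 20)
  g <- sprintf("g%02d", 1:20)
  res3 <- combine_platforms(list(pl1 = make_de(g, fc, p1),
                                 pl2 = make_de(g, fc, p2, "pl2")), icc = NULL)
  text_z <- (qnorm(1 - p1 / 2) + qnorm(1 - p2 / 2)) / sqrt(2)
  expect_equal(res3$z_combined[match(g, res3$gene)], text_z, tolerance = 1e-10)
})

test_that("three-platform fixture matches the independent oracle", {
  p <- c(0.01, 0.20, 0.03); fc <- c(1.5, 0.4, 1.1); ic <- c(0.8, 0.3, 0.9)
  de <- lapply(1:3, function(i) make_de("gA", fc[i], p[i], paste0("pl", i)))
  names(de) <- paste0("pl", 1:3)
  icc <- make_icc("gA", setNames(as.list(ic), paste0("pl", 1:3)))
  res <- combine_platforms(de, icc)
  z <- sign(fc) * qnorm(1 - p / 2)
  w <- abs(fc) * (1 + ic^2)
  z_oracle <- sum(w * z) / sqrt(sum(w^2))
  expect_equal(res$z_combined, z_oracle, tolerance = 1e-10)
  expect_equal(res$p_combined, 2 * pnorm(-abs(z_oracle)), tolerance = 1e-10)
})

test_that("combined Z is invariant to platform order and zero-weight platforms", {
  set.seed(67)
  g <- sprintf("g%02d", 1:10)
  de <- list(pl1 = make_de(g, rnorm(10), runif(10), "pl1"),
             pl2 = make_de(g, rnorm(10), runif(10), "pl2"))
  res_a <- combine_platforms(de, icc = NULL)
  res_b <- combine_platforms(rev(de), icc = NULL)
  expect_equal(res_a$z_combined[order(res_a$gene)],
               res_b$z_combined[order(res_b$gene)], tolerance = 1e-12)
  # a duplicated platform with all-zero fold changes (W = 0) changes nothing
  de$pl3 <- make_de(g, rep(0, 10), runif(10), "pl3")
  res_c <- combine_platforms(de, icc = NULL)
  expect_equal(res_c$z_combined[order(res_c$gene)],
               res_a$z_combined[order(res_a$gene)], tolerance = 1e-12)
})

test_that("all-zero-weight genes and tiny p-values are handled", {
  d <- make_de(c("a", "b"), c(0, 2), c(0.5, 1e-320))
  res <- combine_platforms(list(pl1 = d), icc = NULL)
  ia <- match("a", res$gene); ib <- match("b", res$gene)
  expect_equal(res$z_combined[ia], 0)
  expect_equal(res$p_combined[ia], 1)
  expect_true(is.finite(res$z_combined[ib]) && res$z_combined[ib] > 30)
  expect_true(res$rank[ib] == 1L)
})

test_that("ranks are a deterministic permutation with documented tie-breaks", {
  d <- make_de(c("b", "a", "c"), c(1, 2, 1), c(0.5, 0.5, 0.5))
  res <- combine_platforms(list(pl1 = d), icc = NULL)
  expect_setequal(res$rank, 1:3)
  # equal p: larger |fc| first, then gene id
  expect_equal(res$gene[order(res$rank)], c("a", "b", "c"))
})

test_that("IDR curve counts integration-exclusive discoveries", {
  # every platform Z equal to the combined Z -> IDR 0 everywhere
  g <- sprintf("g%02d", 1:5)
  d <- make_de(g, rep(1, 5), c(0.001, 0.01, 0.05, 0.2, 0.8))
  res <- combine_platforms(list(pl1 = d), icc = NULL)
  ic <- idr_curve(res, z_grid = seq(0, 4, 0.5))
  expect_true(all(ic$idr == 0))
  expect_true(all(ic$idr >= 0 & ic$idr <= 1))

  # constructed: at z = 2, two combined-significant genes, one exclusive
  res2 <- res
  zm <- attr(res2, "z_matrix")
  res2$z_combined <- c(2.5, 2.2, 1.0, 0.5, 0.1)
  zm[, 1] <- c(2.6, 1.2, 1.0, 0.5, 0.1)  # gene 2 sub-threshold on its platform
  attr(res2, "z_matrix") <- zm
  ic2 <- idr_curve(res2, z_grid = 2)
  expect_equal(ic2$n_combined_significant, 2L)
  expect_equal(ic2$n_exclusive, 1L)
  expect_equal(ic2$idr, 0.5)

  # threshold above every |Z|: empty denominator convention
  ic3 <- idr_curve(res, z_grid = 50)
  expect_equal(ic3$idr, 0)
})

test_that("concordance curves count consistently deregulated genes", {
  g <- sprintf("g%02d", 1:6)
  d <- make_de(g, rep(2, 6), seq(0.001, 0.6, length.out = 6))
  res <- combine_platforms(list(pl1 = d), icc = NULL)

  # every dataset strongly up -> fraction 1 at all k
  fc_all <- list(d1 = setNames(rep(2, 6), g), d2 = setNames(rep(2, 6), g))
  cc <- concordance_curve(res, fc_all, k_grid = c(2, 4, 6))
  expect_true(all(cc$fraction == 1))

  # nothing beyond |1| -> 0 at all k
  fc_none <- lapply(fc_all, function(v) v * 0.3)
  expect_true(all(concordance_curve(res, fc_none, k_grid = c(2, 4))$fraction == 0))

  # constructed: genes ranked g01..g06; 3 of the top 4 concordant
  fc1 <- setNames(c(2, 2, -2, 0.5, 2, 0), g)
  fc2 <- setNames(c(2, 1.5, -1.8, 0.2, 0, 2), g)
  cc2 <- concordance_curve(res, list(d1 = fc1, d2 = fc2), k_grid = 4)
  expect_equal(cc2$fraction, 0.75)

  # split directions never reach the same-direction half: with three
  # datasets (half = 2), one up and one down leave no qualifying gene
  fc3 <- setNames(c(2, rep(0, 5)), g)
  fc4 <- setNames(c(-2, rep(0, 5)), g)
  fc5 <- setNames(rep(0, 6), g)
  cc3 <- concordance_curve(res, list(d1 = fc3, d2 = fc4, d3 = fc5), k_grid = 6)
  expect_equal(cc3$fraction, 0)
  # but two of three in the same direction do qualify
  cc4 <- concordance_curve(res, list(d1 = fc3, d2 = fc3, d3 = fc4), k_grid = 6)
  expect_equal(cc4$fraction, 1 / 6)

  expect_error(concordance_curve(res, fc_all[1]), ">= 2 datasets")
})

test_that("top-k selection finds the crossing and falls back to 500", {
  mk_curve <- function(fr, k = seq(100, 500, 100)) {
    structure(data.frame(k = k, fraction = fr),
              class = c("ConcordanceCurve", "data.frame"))
  }
  # identical curves: spread constant -> default
  c1 <- mk_curve(c(0.9, 0.8, 0.7, 0.6, 0.5))
  expect_equal(select_top_k(list(c1, c1)), 500)
  # curves crossing at k = 300
  c2 <- mk_curve(c(0.5, 0.6, 0.7, 0.8, 0.9))
  expect_equal(select_top_k(list(c1, c2)), 300L)
  # single curve -> default
  expect_equal(select_top_k(list(c1), default_k = 500), 500)
  expect_equal(select_top_k(list(c1), default_k = 200), 200)
})
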