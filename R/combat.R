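#' Empirical-Bayes location/scale batch adjustment
#'
#' Parametric empirical-Bayes adjustment for additive and multiplicative
#' batch effects when pooling same-platform datasets: (1) genes are
#' standardized with a least-squares fit on batch plus optional biological
#' covariates; (2) per-batch, per-gene location (`gamma`) and scale
#' (`delta^2`) effects are estimated; (3) estimates are shrunk toward
#' batch-level hyperpriors (normal for `gamma`, inverse-gamma for
#' `delta^2`, hyperparameters by method of moments) through the iterative
#' conditional posterior update; (4) the shrunk effects are removed and
#' the covariate/mean/scale structure restored.
#'
#' @param values numeric matrix, genes x samples (log scale).
#' @param batch per-sample batch labels (>= 2 batches of >= 2 samples,
#'   unless `passthrough = TRUE` with a single batch).
#' @param covariates optional per-sample biological factor (e.g. group)
#'   protected during adjustment; must not be confounded with batch.
#' @param conv convergence tolerance on the relative parameter change of
#'   the EB update (default 1e-6), capped at `max_iter` iterations.
#' @param max_iter iteration cap (default 5000).
#' @param passthrough with a single batch, return the input unchanged
#'   instead of erroring.
#' @return list with `adjusted` (matrix) and `model` (a `BatchModel` list
#'   carrying `gamma_star`, `delta2_star`, standardization parameters and
#'   iteration counts).
#' @references Johnson, Li & Rabinovic (2007) Biostatistics 8:118-127.
#' @export
combat_adjust <- function(values, batch, covariates = NULL,
                          conv = 1e-6, max_iter = 5000, passthrough = FALSE) {
  values <- as.matrix(values)
  batch <- factor(batch)
  assert_that(length(batch) == ncol(values), "one batch label per sample")
  if (nlevels(batch) < 2) {
    if (passthrough) {
      cx_log("single batch: passthrough, values unchanged")
      return(list(adjusted = values, model = NULL))
    }
    cx_stop("need >= 2 batches (or passthrough = TRUE)")
  }
  nb <- table(batch)
  if (any(nb < 2)) {
    cx_stop("every batch needs >= 2 samples; offending batch(es): ",
            paste(names(nb)[nb < 2], collapse = ", "))
  }

  n <- ncol(values)
  G <- nrow(values)
  batch_design <- stats::model.matrix(~ 0 + batch)
  design <- batch_design
  if (!is.null(covariates)) {
    mod <- stats::model.matrix(~ factor(covariates))
    design <- cbind(batch_design, mod[, -1, drop = FALSE])
  }
  if (qr(design)$rank < ncol(design)) {
    cx_stop("design is rank-deficient: covariates confounded with batch")
  }
  n_batch <- nlevels(batch)

  ## Gene-wise least squares and standardization
  B_hat <- solve(crossprod(design), t(design) %*% t(values))
  grand_mean <- crossprod(as.numeric(nb) / n, B_hat[seq_len(n_batch), , drop = FALSE])
  var_pooled <- rowSums((values - t(design %*% B_hat))^2) / n
  var_pooled <- pmax(var_pooled, 1e-12)

  stand_mean <- matrix(grand_mean, G, n)
  if (ncol(design) > n_batch) {
    tmp <- design
    tmp[, seq_len(n_batch)] <- 0
    stand_mean <- stand_mean + t(tmp %*% B_hat)
  }
  s_data <- (values - stand_mean) / sqrt(var_pooled)

  ## Batch effect estimates and EB hyperpriors (method of moments)
  gamma_hat <- matrix(NA_real_, G, n_batch)
  delta2_hat <- matrix(NA_real_, G, n_batch)
  for (b in seq_len(n_batch)) {
    idx <- which(batch == levels(batch)[b])
    gamma_hat[, b] <- rowMeans(s_data[, idx, drop = FALSE])
    delta2_hat[, b] <- apply(s_data[, idx, drop = FALSE], 1, stats::var)
  }
  gamma_bar <- colMeans(gamma_hat)
  t2 <- apply(gamma_hat, 2, stats::var)
  m <- colMeans(delta2_hat)
  s2 <- apply(delta2_hat, 2, stats::var)
  a_prior <- (2 * s2 + m^2) / s2
  b_prior <- (m * s2 + m^3) / s2

  gamma_star <- gamma_hat
  delta2_star <- delta2_hat
  iters <- integer(n_batch)
  for (b in seq_len(n_batch)) {
    idx <- which(batch == levels(batch)[b])
    nb_b <- length(idx)
    sdat <- s_data[, idx, drop = FALSE]
    g_old <- gamma_hat[, b]
    d_old <- delta2_hat[, b]
    it <- 0L
    repeat {
      it <- it + 1L
      g_new <- (t2[b] * nb_b * gamma_hat[, b] + d_old * gamma_bar[b]) /
        (t2[b] * nb_b + d_old)
      sum2 <- rowSums((sdat - g_new)^2)
      d_new <- (0.5 * sum2 + b_prior[b]) / (nb_b / 2 + a_prior[b] - 1)
      change <- max(abs(g_new - g_old) / pmax(abs(g_old), 1e-12),
                    abs(d_new - d_old) / d_old)
      g_old <- g_new
      d_old <- d_new
      if (change < conv || it >= max_iter) break
    }
    if (it >= max_iter) {
      warning("EB update for batch ", levels(batch)[b],
              " stopped at iteration cap ", max_iter)
    }
    gamma_star[, b] <- g_old
    delta2_star[, b] <- d_old
    iters[b] <- it
  }

  adjusted <- s_data
  for (b in seq_len(n_batch)) {
    idx <- which(batch == levels(batch)[b])
    adjusted[, idx] <- (s_data[, idx, drop = FALSE] - gamma_star[, b]) /
      sqrt(delta2_star[, b])
  }
  adjusted <- adjusted * sqrt(var_pooled) + stand_mean
  dimnames(adjusted) <- dimnames(values)

  model <- structure(list(
    batches = levels(batch),
    gamma_star = gamma_star,
    delta2_star = delta2_star,
    gamma_hat = gamma_hat,
    delta2_hat = delta2_hat,
    grand_mean = as.numeric(grand_mean),
    var_pooled = var_pooled,
    hyper = list(gamma_bar = gamma_bar, t2 = t2,
                 a_prior = a_prior, b_prior = b_prior),
    iterations = iters
  ), class = "BatchModel")

  list(adjusted = adjusted, model = model)
}
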