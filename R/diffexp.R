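#' Moderated t-statistics for a two-group comparison
#'
#' Gene-wise (optionally precision-weighted) least-squares two-group fit
#' with empirical-Bayes variance moderation: residual variances `s2_g`
#' are shrunk toward a common prior via
#' `s2_post = (d0 * s0^2 + d_g * s2_g) / (d0 + d_g)`, with prior degrees
#' of freedom `d0` and prior variance `s0^2` estimated by matching
#' moments of the log residual variances (scaled-F model).  The moderated
#' t is the fold change over its moderated standard error, referred to a
#' t distribution with `d_g + d0` degrees of freedom.
#'
#' Degenerate genes with zero residual variance in both groups are
#' reported with `t = 0`, `p = 1` and the fold change as computed.
#'
#' @param values numeric matrix, genes x samples (log2 scale).
#' @param groups two-level factor (or coercible); the *second* level is
#'   treated as the case group, so `log2fc` = case mean - control mean.
#' @param weights optional positive precision-weight matrix, same
#'   dimension as `values` (e.g. from [voom_transform()]).
#' @param d0 override for the prior degrees of freedom; `d0 = 0` recovers
#'   the ordinary two-sample t.  Default `NULL` estimates it from the
#'   data; an infinite estimate is capped at 1e6.
#' @param platform_id,comparison optional labels stored on the result.
#' @return a `DEResult` data.frame with columns `gene`, `log2fc`, `t`,
#'   `df`, `p`, `q`, plus attributes `platform_id`, `comparison`,
#'   `n_case`, `n_control`, `df_prior`, `s2_prior`.
#' @export
moderated_t <- function(values, groups, weights = NULL, d0 = NULL,
                        platform_id = NA_character_,
                        comparison = NA_character_) {
  values <- as.matrix(values)
  groups <- factor(groups)
  keep <- !is.na(groups)
  values <- values[, keep, drop = FALSE]
  groups <- droplevels(groups[keep])
  if (!is.null(weights)) weights <- as.matrix(weights)[, keep, drop = FALSE]
  assert_that(nlevels(groups) == 2, "groups must have exactly two levels")
  n_tab <- table(groups)
  if (any(n_tab < 2)) {
    cx_stop("each group needs >= 2 samples; got ",
            paste(sprintf("%s=%d", names(n_tab), n_tab), collapse = ", "))
  }
  n <- ncol(values)
  G <- nrow(values)
  if (is.null(weights)) weights <- matrix(1, G, n)
  assert_that(all(weights > 0), "weights must be strictly positive")

  is_case <- groups == levels(groups)[2]
  w1 <- weights[, !is_case, drop = FALSE]; x1 <- values[, !is_case, drop = FALSE]
  w2 <- weights[, is_case, drop = FALSE];  x2 <- values[, is_case, drop = FALSE]
  sw1 <- rowSums(w1); sw2 <- rowSums(w2)
  m1 <- rowSums(w1 * x1) / sw1
  m2 <- rowSums(w2 * x2) / sw2
  beta <- m2 - m1
  rss <- rowSums(w1 * (x1 - m1)^2) + rowSums(w2 * (x2 - m2)^2)
  df_res <- n - 2
  assert_that(df_res >= 1, "zero residual degrees of freedom")
  s2 <- rss / df_res
  unscaled_var <- 1 / sw1 + 1 / sw2

  if (is.null(d0)) {
    fit <- fit_f_dist(s2, df_res)
    d0 <- fit$df_prior
    s02 <- fit$s2_prior
  } else {
    assert_that(d0 >= 0, "d0 must be non-negative")
    s02 <- if (d0 > 0) fit_f_dist(s2, df_res)$s2_prior else NA_real_
  }
  d0 <- min(d0, 1e6)

  s2_post <- if (d0 > 0) (d0 * s02 + df_res * s2) / (d0 + df_res) else s2
  tt <- beta / sqrt(s2_post * unscaled_var)
  df_total <- df_res + d0
  p <- 2 * stats::pt(-abs(tt), df = df_total)

  ## degenerate rule: no residual variation in either group
  zero_var <- s2 == 0
  tt[zero_var] <- 0
  p[zero_var] <- 1

  q <- bh_adjust(p)
  res <- data.frame(
    gene = rownames(values) %||% as.character(seq_len(G)),
    log2fc = unname(beta),
    t = unname(tt),
    df = df_total,
    p = unname(p),
    q = unname(q),
    stringsAsFactors = FALSE
  )
  attr(res, "platform_id") <- platform_id
  attr(res, "comparison") <- comparison
  attr(res, "n_case") <- sum(is_case)
  attr(res, "n_control") <- sum(!is_case)
  attr(res, "df_prior") <- d0
  attr(res, "s2_prior") <- s02
  class(res) <- c("DEResult", "data.frame")
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Moment estimation of the scaled-F hyperprior for gene variances:
## matches mean and variance of log(s2) against the theoretical moments
## of log chi-square ratios, giving prior df (via the inverse trigamma)
## and prior variance.  Zero variances are excluded from estimation.
fit_f_dist <- function(s2, df) {
  ok <- s2 > 0 & is.finite(s2)
  if (sum(ok) < 2) {
    return(list(df_prior = 1e6, s2_prior = stats::median(s2[ok]) %||% 1))
  }
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  e_mean <- mean(e)
  e_var <- stats::var(e) - trigamma(df / 2)
  if (is.finite(e_var) && e_var > 0) {
    df_prior <- 2 * trigamma_inverse(e_var)
    s2_prior <- exp(e_mean + digamma(df_prior / 2) - log(df_prior / 2))
  } else {
    ## all variances exchangeable: infinite prior df, pooled variance
    df_prior <- 1e6
    s2_prior <- mean(s2[ok])
  }
  list(df_prior = df_prior, s2_prior = s2_prior)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `q_(i) = min_{j >= i} ( m * p_(j) / j )`, capped at 1, returned in the
#' input order.  Controls the false discovery rate for independent or
#' positively dependent tests.
#'
#' @param p vector of p-values in (0, 1].
#' @return adjusted q-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  assert_that(all(p > 0 & p <= 1), "p-values must lie in (0, 1]")
  m <- length(p)
  if (m == 0) return(numeric(0))
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(1, cummin(m / (m:1) * p[o]))[ro]
  q
}
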