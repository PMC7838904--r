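#' Kaplan-Meier estimates per group
#'
#' Product-limit estimator for each group: `S(0) = 1`, right-continuous
#' steps at event times.
#'
#' @param times non-negative follow-up times.
#' @param events event indicators (1 = event, 0 = censored).
#' @param groups per-sample group labels (single group if omitted).
#' @return data.frame with columns `group`, `time`, `n_risk`, `n_event`,
#'   `n_censor`, `survival`, including the `time = 0` anchor row.
#' @export
km_estimate <- function(times, events, groups = NULL) {
  assert_that(all(times >= 0), "times must be non-negative")
  assert_that(all(events %in% c(0, 1)), "events must be 0/1")
  if (is.null(groups)) groups <- rep("all", length(times))
  groups <- factor(groups)
  assert_that(all(table(groups) > 0), "groups must be non-empty")
  fit <- survival::survfit(
    survival::Surv(times, events) ~ g,
    data = data.frame(times = times, events = events, g = groups)
  )
  sm <- summary(fit, censored = TRUE)
  grp <- if (is.null(sm$strata)) {
    rep(levels(groups)[1], length(sm$time))
  } else {
    sub("^g=", "", as.character(sm$strata))
  }
  out <- data.frame(
    group = grp, time = sm$time, n_risk = sm$n.risk, n_event = sm$n.event,
    n_censor = sm$n.censor, survival = sm$surv, stringsAsFactors = FALSE
  )
  anchors <- do.call(rbind, lapply(levels(groups), function(g) {
    data.frame(group = g, time = 0, n_risk = sum(groups == g), n_event = 0,
               n_censor = 0, survival = 1, stringsAsFactors = FALSE)
  }))
  out <- rbind(anchors, out)
  out <- out[order(out$group, out$time), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Two-group log-rank test
#'
#' Standard unweighted log-rank statistic comparing survival
#' distributions between groups.
#'
#' @inheritParams km_estimate
#' @return list with `chisq`, `df`, `p`.
#' @export
logrank_test <- function(times, events, groups) {
  groups <- factor(groups)
  assert_that(nlevels(groups) >= 2, "log-rank needs >= 2 groups")
  sd <- survival::survdiff(
    survival::Surv(times, events) ~ g,
    data = data.frame(times = times, events = events, g = groups)
  )
  df <- length(sd$n) - 1
  list(chisq = unname(sd$chisq), df = df,
       p = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Univariate Cox proportional-hazards fit for a binary grouping
#'
#' Partial-likelihood fit with Efron tie handling (Newton-Raphson to a
#' tight tolerance).  Monotone-likelihood separation (all events ordered
#' by group) is flagged and the confidence interval reported unbounded.
#'
#' @param times,events as in [km_estimate()].
#' @param group_indicator two-level grouping; the hazard ratio is for the
#'   second level over the first.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return list with `hr`, `ci_low`, `ci_high`, `wald_p`, `beta`, `se`,
#'   `monotone` flag.
#' @export
cox_univariate <- function(times, events, group_indicator, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  g <- factor(group_indicator)
  assert_that(nlevels(g) == 2, "group indicator must have exactly two levels")
  ev_by_g <- tapply(events, g, sum)
  if (any(ev_by_g < 1)) {
    cx_stop("both groups need >= 1 event; got ",
            paste(sprintf("%s=%d", names(ev_by_g), ev_by_g), collapse = ", "))
  }
  fit <- survival::coxph(
    survival::Surv(times, events) ~ g,
    data = data.frame(times = times, events = events, g = g),
    ties = ties,
    control = survival::coxph.control(eps = 1e-10, iter.max = 100)
  )
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(fit$var[1, 1]))
  monotone <- !is.finite(beta) || abs(beta) > 15 || !is.finite(se) || se > 100
  if (monotone) {
    warning("monotone likelihood: hazard ratio unbounded, CI unreliable")
    return(list(hr = exp(beta), ci_low = 0, ci_high = Inf, wald_p = NA_real_,
                beta = beta, se = se, monotone = TRUE))
  }
  z <- beta / se
  list(
    hr = exp(beta),
    ci_low = exp(beta - stats::qnorm(0.975) * se),
    ci_high = exp(beta + stats::qnorm(0.975) * se),
    wald_p = 2 * stats::pnorm(-abs(z)),
    beta = beta, se = se, monotone = FALSE
  )
}

#' Stratify survival by the best-performing expression cutoff
#'
#' Scans integer percentiles 25 to 75 of a gene's expression; at each,
#' samples at or above the cutoff form the high group, the two-group
#' log-rank p-value is computed, and the percentile minimizing p is
#' selected (ties resolved toward the percentile closest to the median,
#' then the lower one).  The returned fit carries the Kaplan-Meier
#' curves, log-rank test and univariate Cox summary (high vs low) at the
#' chosen cutoff.
#'
#' The selected p-value is the minimum over a scan and is therefore
#' anti-conservative as a hypothesis test; it is reported raw, as is
#' conventional for this procedure, and should be read as descriptive.
#'
#' @param expr named numeric vector of expression values (names =
#'   sample ids).
#' @param surv survival table (`sample_id`, `time`, `event`); only
#'   samples present in both inputs are used (>= 10 required, with >= 1
#'   event).
#' @param percentiles integer percentiles to scan (default `25:75`).
#' @param gene optional gene id stored on the result.
#' @return a `SurvivalFit` list: `gene`, `cutoff_percentile`,
#'   `cutoff_value`, `n_low`, `n_high`, `logrank_chisq`, `logrank_p`,
#'   `km`, `cox`, `scan` (percentile / cutoff / p table).
#' @export
best_cutoff_stratify <- function(expr, surv, percentiles = 25:75, gene = NA_character_) {
  surv <- validate_survival_table(surv)
  common <- intersect(names(expr), surv$sample_id)
  assert_that(length(common) >= 10, "need >= 10 samples with both expression and survival")
  e <- expr[common]
  s <- surv[match(common, surv$sample_id), ]
  assert_that(sum(s$event) >= 1, "need >= 1 observed event")
  if (stats::sd(e) == 0) cx_stop("constant expression: no valid split")

  scan <- data.frame(percentile = percentiles,
                     cutoff = NA_real_, p = NA_real_)
  for (i in seq_along(percentiles)) {
    cut <- stats::quantile(e, percentiles[i] / 100, names = FALSE)
    high <- e >= cut
    if (all(high) || !any(high)) next  # degenerate split, skipped
    lr <- logrank_test(s$time, s$event, ifelse(high, "high", "low"))
    scan$cutoff[i] <- cut
    scan$p[i] <- lr$p
  }
  if (all(is.na(scan$p))) cx_stop("every candidate split was degenerate")

  ok <- which(!is.na(scan$p))
  best <- ok[order(scan$p[ok], abs(scan$percentile[ok] - 50), scan$percentile[ok])][1]
  cut <- scan$cutoff[best]
  high <- e >= cut
  grp <- factor(ifelse(high, "high", "low"), levels = c("low", "high"))
  lr <- logrank_test(s$time, s$event, grp)
  cox <- cox_univariate(s$time, s$event, grp)

  structure(list(
    gene = gene,
    cutoff_percentile = scan$percentile[best],
    cutoff_value = cut,
    n_low = sum(!high), n_high = sum(high),
    logrank_chisq = lr$chisq, logrank_p = lr$p,
    km = km_estimate(s$time, s$event, grp),
    cox = cox,
    scan = scan
  ), class = "SurvivalFit")
}

#' @export
print.SurvivalFit <- function(x, ...) {
  cat(sprintf(
    paste0("SurvivalFit%s: cutoff at percentile %d (value %.4g)\n",
           "  groups: low n = %d, high n = %d\n",
           "  log-rank chisq = %.3f, p = %.3g\n",
           "  Cox HR (high vs low) = %.3f [%.3f, %.3f], Wald p = %.3g\n"),
    if (is.na(x$gene)) "" else paste0(" for ", x$gene),
    x$cutoff_percentile, x$cutoff_value, x$n_low, x$n_high,
    x$logrank_chisq, x$logrank_p,
    x$cox$hr, x$cox$ci_low, x$cox$ci_high, x$cox$wald_p
  ))
  invisible(x)
}
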