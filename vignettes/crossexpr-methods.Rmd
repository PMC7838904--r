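---
title: "Methods: cross-platform integration of differential expression evidence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-platform integration of differential expression evidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Public transcriptomics repositories hold many prostate-cancer expression
cohorts measured on incompatible platforms (several microarray generations
plus RNA-seq), each covering a different gene universe and carrying its own
laboratory signature. Meta-analysing only the genes present on every
platform discards exactly the poorly covered genes one would like to rescue;
naive pooling confounds biology with batch. `crossexpr` implements a
raw-abundance integration workflow that (a) harmonizes each dataset to
gene-level log-scale expression, (b) removes batch structure within a
platform, (c) computes per-platform differential expression, and (d) merges
the per-platform evidence per gene over *exactly the platforms that measured
it*, so single-platform genes are retained rather than lost.

# The combination model

For a two-group comparison, each platform $i$ yields a log2 fold change
$\mathrm{FC}_i$ and a two-sided p-value $p_i$ from a moderated t-test.
These become signed normal scores

$$Z_i = \mathrm{sign}(\mathrm{FC}_i)\,\Phi^{-1}(1 - p_i/2),$$

which are combined with the weighted (Liptak–Stouffer) rule

$$Z = \frac{\sum_i W_i Z_i}{\sqrt{\sum_i W_i^2}},\qquad
  W_i = |\mathrm{FC}_i|\,(1 + \mathrm{ICC}_i^2).$$

The weight rewards both effect magnitude and cross-platform
reproducibility. The integrative correlation coefficient (ICC) of gene $g$
for a platform pair is the Pearson correlation between $g$'s
correlation profiles — the vectors of within-platform correlations between
$g$ and every other shared gene — computed in the two platforms. A gene
whose co-expression pattern replicates across technologies scores near 1;
an artifact scores near 0. With more than two platforms the per-platform
ICC entering $W_i$ is the mean of the pairwise ICCs involving that
platform; a gene measured on a single platform has no reproducibility
evidence and gets ICC 0 (so $W = |\mathrm{FC}|$, and its combined p-value
equals its single-platform p-value). A negative ICC is allowed and enters
only as its square, per the weight formula.

Two diagnostics summarize the gain from integration:

* **IDR curve** — at each threshold $z$, the fraction of
  combined-significant genes ($|Z| \ge z$) that no contributing platform
  detects on its own: discoveries owed to integration.
* **Concordance curve** — for the top-$k$ of the combined ranking, the
  fraction of genes with $|\log_2 \mathrm{FC}| > 1$ in the same direction
  in at least half of the contributing datasets. Curves for the stage
  comparisons are overlaid and the hallmark list size $k$ is chosen where
  they cross; `select_top_k()` operationalizes "where the curves cross" as
  the grid point minimizing the spread (max − min) of the curves, falling
  back to 500 for a single curve or an all-equal spread. Ties among
  minimizers resolve toward the default, then the smaller $k$.

The per-comparison top-$k$ sets are intersected into a molecular
alteration map (MAM): each region is a Boolean membership pattern over the
stage comparisons (e.g. "in tumor-vs-normal but not tumor-vs-HGPIN"), and
each gene in the union of top-$k$ sets is assigned to every region whose
pattern it satisfies, with per-comparison direction from the sign of the
combined $Z$. The shipped `default_region_spec()` is a *reconstruction* of
the natural stage regions, not a printed ground truth; region patterns are
user-configurable data, and genes matching no pattern land in an explicit
`unassigned` bin so the cover is closed.

# Upstream modelling choices

**Moderated t.** Gene-wise two-group (optionally precision-weighted) least
squares; residual variances are shrunk through
$\tilde s^2_g = (d_0 s_0^2 + d_g s^2_g)/(d_0 + d_g)$ with $(d_0, s_0^2)$
estimated by matching the mean and variance of $\log s^2_g$ to the
scaled-F model (inverse-trigamma closed form). An infinite prior-df
estimate is capped at $10^6$; genes with zero residual variance in both
groups are reported with $t = 0$, $p = 1$ rather than borrowing a purely
prior-driven denominator. With $d_0 = 0$ the ordinary two-sample t is
recovered exactly — both limits are tested, and the full statistic is
oracle-checked against an independent implementation.

**Batch adjustment.** The parametric empirical-Bayes location/scale model:
standardize per gene with a batch + covariate least-squares fit; estimate
per-batch per-gene location $\gamma$ and scale $\delta^2$; shrink via
normal and inverse-gamma hyperpriors (method of moments) with the
iterative conditional posterior update (tolerance $10^{-6}$, cap 5000
iterations; fixtures converge in under 20). Biological group is protected
as a covariate when available. Two intrinsic properties of this algorithm
are worth knowing: per-gene *empirical* batch-mean differences retain
finite-sample noise after adjustment (only the systematic component is
removed), and the protected covariate's pooled effect estimate is added
back unscaled, so its estimation noise slightly re-inflates the variance
of the batch whose residuals were scaled down. Tests therefore assert the
systematic location component and the variance-ratio band on the
covariate-free design, and effect preservation (within 5%) on the
covariate design.

**Count data.** `voom_transform()` computes
$\log_2\!\big((c + 0.5)/(L + 1)\cdot 10^6\big)$ and fits a lowess trend
(span 0.5) of $\sqrt{s_g}$ against mean log2 count, evaluated at fitted
per-observation log-counts with linear extrapolation and a $10^{-6}$
floor; weights are the inverse fourth power. One trend is fitted per
dataset (fitting per comparison is an equally defensible alternative; per
dataset is the stabler choice and is documented as such). The log-CPM agrees with
the closed form to $10^{-12}$ and weights correlate > 0.999 with the
reference implementation on negative-binomial fixtures.

**Quantile normalization.** Columns are mapped onto the row-wise mean of
the column-sorted matrix; tied values receive the mean of the
corresponding reference values (linear interpolation at average ranks).
Idempotence holds exactly on tie-free data; with ties the second pass can
move values within a tie group — a known property of the average-rank
dialect.

**Probe collapsing.** One probe per gene, chosen by maximal sample
standard deviation (denominator $n-1$), ties broken toward the
lexicographically smallest probe id for determinism.

**Filters.** Tumor-bearing samples need tumor content ≥ 0.40 (inclusive:
"minimum acceptable"); unknown content passes (content prediction was
never universal) and is logged. Stromal gene lists are removed as a set
union before integration. PCA outlier flagging (median ± 4 MAD on the
first 3 components) is conservative plumbing standing in for interactive
cluster inspection; it makes no claim to replicate manual dataset
curation.

**Survival.** The best-performing cutoff scans integer percentiles 25–75
(step 1 — "successive percentiles" with an unstated step), dichotomizes at
expression ≥ cutoff, and minimizes the log-rank p (ties → closest to the
median, then lower). The selected p is reported raw, as is conventional
for this procedure; the suite demonstrates its anti-conservativeness under
the null (null rejection well above 5%), so it should be read as
descriptive, not confirmatory. Cox fits use Efron ties via the `survival`
package with a $10^{-10}$ Newton tolerance.

# The synthetic world

`generate_multiplatform()` states the testing world once:

| setting | default | rationale |
|---|---|---|
| genes | 5000 | enough for stable ICC and BH behaviour |
| platforms × datasets | 3 × 2 | smallest design with nontrivial ICC pairs and batches |
| samples/group | 15 | typical cohort arm in public prostate datasets |
| DE fraction | 4% | a few hundred planted genes per comparison |
| effect sizes | lognormal(0, 0.5), random sign | heavy enough tail to exercise ranking |
| baseline | N(7, 1.5) | log2 array intensity scale |
| batch location | centers N(0, 0.5), per-gene N(center, 0.5) | cross-study array shifts are gene-specific and comparable to biology; per-gene SD 0.5 gives a planted-vs-recovered correlation ceiling ≈ 0.93 at 30 samples/batch |
| batch scale | lognormal(0, 0.3) per gene | spans the ×1.5 scale regime |
| coverage | 80% per platform | forces partially disjoint universes |
| noise SD | U(0.7, 1.3) per platform | platform heterogeneity |
| tumor content | Beta(8, 3) for tumor samples | mean ≈ 0.73, a realistic purity spread with mass below 0.40 |

With `admixture = TRUE`, planted effects in tumor-bearing samples are
attenuated by the sample's tumor fraction — the mechanism that makes the
tumor-content filter matter. Platforms marked `rnaseq` additionally emit
negative-binomial counts (mean $2^x$, dispersion 0.1) for the count
transform. All randomness derives from one seed through pre-drawn
sub-stream seeds, so any dataset can be regenerated independently and
equal seeds give byte-identical output.

What the generator does *not* emulate: probe-level array physics, GC/length
bias, annotation errors, dependence between genes beyond the planted
effects, non-proportional hazards. A green suite therefore establishes
that the algorithms do what their formulas say and that integration beats
single platforms *in this stated world* — not that the biological findings
of any particular cohort reproduce.

# Numerical conventions and degenerate inputs

* p → Z uses the two-sided construction with the fold-change sign;
  $p = 0$ is clamped to the smallest positive double (logged).
* Genes with all-zero weights get $Z = 0$, $p = 1$ (logged);
  an empty IDR denominator yields IDR 0.
* Rank ties break by descending mean |log2FC|, then gene id — output is a
  deterministic permutation.
* Zero-variance genes get ICC 0 (logged); an ICC pair needs ≥ 3 shared
  genes.
* Consistent deregulation requires a common direction in the qualifying
  half of datasets (the stricter reading of "> 1 or < −1 in at least half").
* The "at least half" count is taken over all datasets contributing to the
  comparison, rounded up.

# Design choices where the design was open

* **CLI surface.** The shell entry point exposes `simulate` and `run-all`
  (exit codes 0/2/3); the individual stages are exported R functions.
  Driving each stage through TSV files from the shell would duplicate the
  R API without adding capability.
* **Concordance exclusions.** Comparisons involving HGPIN are excluded
  from concordance/top-k selection in the pipeline (a single-cohort
  phenotype cannot support a cross-dataset concordance claim); their
  integrated rankings are still produced.
* **Effect-strength assessment.** Sample similarity is Pearson correlation
  over shared genes (scale-invariant); the Kolmogorov–Smirnov test is
  two-sided with the direction established separately by medians.
* **k-selection tie-breaks** and the min-spread crossing rule are this
  package's operationalization of a visual procedure.

# Known limitations

* Two-group designs only; no general contrasts, duplicate correlation, or
  multivariate survival models.
* The EB batch adjustment assumes the location/scale model; it will not
  remove batch-by-group interactions, and with protected covariates the
  reconstruction property described above applies.
* The minimum-p cutoff is anti-conservative by construction.
* ICC near zero does not distinguish "irreproducible" from "no
  co-expression structure"; with small shared universes the null |ICC|
  scale is $\sqrt{2/\pi(m-1)}$, which the tests account for.
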