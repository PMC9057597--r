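---
title: "Modelling dynamic differential expression in time-course RNA-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling dynamic differential expression in time-course RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trendcurve)
```

## The problem

A time-course RNA-seq experiment asks a different question than a two-group
comparison: not *whether* a gene changes, but *when* it departs from its
resting state, in which direction, and whether the trend later reverses.
Factorial tools answer the first question time point by time point and lose
the temporal ordering; strongly parametric trajectory models (monotone or
single-impulse shapes) miss multiphasic responses, such as an acute
activation followed by a counter-regulatory decline.  trendcurve takes a
middle road: it models each gene's trajectory nonparametrically with a
penalized negative-binomial smoother and asks, at every time point, whether
the fitted mean has left the gene's own baseline fluctuation band.  Genes
that do are *dynamic differentially expressed genes* (DDEGs).

## The model, step by step

**Baseline fluctuation interval.**  Counts of gene $i$ at the user-defined
baseline time follow $X \sim \mathrm{NB}(\mu_i, \varphi_i)$ with the
quadratic mean–variance relation $\sigma^2 = \mu + \varphi\mu^2$.  With
$\varphi$ held fixed, the NB likelihood's score in $\mu$ is
$\sum_j (x_j-\mu)/(\mu(1+\varphi\mu))$, so the maximum-likelihood mean is
the baseline sample mean regardless of $\varphi$.  The 90% fluctuation
interval is the pair of discrete 5% and 95% quantiles of
$\mathrm{NB}(\hat\mu, \hat\varphi)$; discrete quantiles make its exact
probability content at least the nominal level.

**Dispersion.**  $\varphi_i$ is estimated once per gene, pooling all time
groups so that the time trend itself is not mistaken for overdispersion.  A
df-weighted method-of-moments average of $(s^2_g - \bar{x}_g)/\bar{x}_g^2$
across groups provides the start; the estimate then solves the Pearson
$\chi^2$ matching equation
$\sum_g \sum_j (x_{gj}-\bar x_g)^2 / (\bar x_g + \varphi \bar x_g^2) = \sum_g (n_g - 1)$
with group means fixed.  For a single group this reproduces the
method-of-moments value exactly; across heteroscedastic groups it pools on
the correct scale.  We chose this quasi-likelihood refinement over an
adjusted-profile-likelihood one after finding that the latter sits
systematically below the moment estimator at the 3-replicate group sizes
this design targets, which would inflate baseline-band significance.  The
estimate is clamped to $[10^{-8}, 10]$; dispersions below $10^{-12}$ are
treated as the Poisson limit throughout so that tails and quantiles remain
exact as $\varphi \to 0$.

**Trajectory smoother.**  Non-baseline counts are fitted by a penalized NB
regression with one log-mean coefficient per distinct time and a
second-divided-difference roughness penalty — a discrete smoothing spline.
The fit minimizes $-L + \lambda J(\eta)$ where $\eta(t) = \log \mu(t)$ and
$J$ sums squared second divided differences over the (possibly uneven) time
grid.  The classical $\mathrm{NB}(\alpha, p(t))$ logit-link formulation is
the same model via $\alpha = 1/\varphi$, $p(t) = 1/(1+\varphi\mu(t))$; we
fit on $\log\mu$ because it is the numerically standard parametrization.
$\lambda$ is chosen per gene by generalized cross-validation over a
log-spaced grid ($10^{-3}$ to $10^3$, 13 points by default; AIC is
available as an option).  The solve is an iteratively reweighted
least-squares loop whose normal equations are a small $m \times m$ system
($m$ = number of distinct non-baseline times), so the whole pipeline is a
few milliseconds per gene and deterministic.  As $\lambda \to 0$ the fit
reduces to the per-time NB means (the per-time sample means), which is also
the fallback when only one non-baseline time exists or the loop fails to
converge.  Baseline samples never enter the smoother: they only define the
baseline model, so the trajectory is judged against an independently
estimated resting state.

**Dynamic significance.**  At each non-baseline time the fitted mean is
referred to the baseline law: $p_t = P(X \ge \lceil \hat\mu_t \rceil)$ when
the fitted mean is above baseline, $P(X \le \lfloor \hat\mu_t \rfloor)$
below.  Rounding outward onto the discrete support is conservative and
well-defined for a continuous fitted mean on a count distribution; whether
the boundary value itself should be included has no canonical answer on a
discrete law, and we document ours rather than claim it is the only one.  A
zero baseline mean (nothing observed at rest) has no NB law; we substitute
a pseudo-mean of 0.5 counts and flag the gene.  Per-time p-values are
combined with Fisher's method ($-2\sum\log p \sim \chi^2_{2K}$; exact zeros
floored at $10^{-300}$), and gene-level p-values are Holm–Bonferroni
adjusted across genes, within one analysis unit (one cell type, one
severity group) rather than across units.  A gene is a DDEG when the
adjusted p-value is below $\alpha = 0.05$.  For pattern segmentation (below)
the *raw* per-time p-values at 0.05 are used instead: segmentation is a
descriptive labelling of an already-significant gene, and adjusted per-time
thresholds would erase the anchors of genuinely dynamic genes.  Both
thresholds are exposed.

Because the fitted mean at a time point aggregates several replicates and
neighbouring times, its sampling variance is smaller than that of the
single draw the baseline law describes; the per-time p-values are therefore
conservative under the null, which is the intended direction for a
screening statistic (the Type-I check below confirms the Holm-adjusted
false flag rate stays under $\alpha$).

## Break points and patterns

The significant times (raw $p_t < 0.05$), with the baseline prepended as
start anchor, are connected in order; non-significant times are skipped
rather than interpolated — a point indistinguishable from baseline carries
no trend information, and connecting across it matches how one reads the
fitted curve.  An interior time strictly above both neighbours is a peak
(type I: up then down), strictly below both a trough (type II).  Ties
continue the previous direction, mirroring the strict inequalities in the
definition.  Segments between consecutive anchors are labelled by the sign
of the fitted-mean change, giving a master pattern (`up_down`) and an
anchored sub-pattern (`0D-2D up, 2D-14D down`).  Peaks and troughs
necessarily alternate.

## Pathway summaries: the TimeHeatmap

For every consecutive time window $[t_{j-1}, t_j]$ the DDEGs whose fitted
$\log_2(\mu+1)$ changed by more than 0.25 are collected as up- or
down-moving; the pseudo-count bounds the change for near-zero means and the
0.25 default suppresses jitter membership while leaving biologically
interesting half-log2 shifts intact (it is configurable).  Each window's
up and down lists are tested for over-representation in each gene set with
the one-sided Fisher exact test over the preprocessing-surviving universe;
the union of every window's top-10 sets (ranked by enrichment p, as the
heatmap is a ranking display; Holm-adjusted values are reported alongside)
forms the heatmap rows.  A cell holds `Avg_log2FC`, the mean per-window
change of the pathway's moving DDEGs (window-specific membership by
default; averaging over all pathway DDEGs is a switch), and rows are
annotated with the DDEG count, the percentage of the pathway that is
dynamic, and `GO_mean_logFC`, the row-sum of `Avg_log2FC` — an accumulated
course-long change that ranks pathways for the two-sided bar display.
Cells are per-window deltas; the group-comparison curves below are
baseline-relative, matching what each display is meant to show.

## Comparing groups over time

To ask *when* two groups (say disease severities) diverge on a pathway, the
pooled baseline-relative $\log_2$ fold-change profiles of the pathway's
DDEGs are smoothed per group with LOESS (span 0.75, local-linear; pooling
profiles into one scatter is deliberate — the smooth describes the pathway,
not any single gene).  The shared time range is tiled into 100 intervals
and each interval's divergence is the area ratio
$|\int(A-B)| / (|\int A| + |\int B| + 10^{-9})$ — symmetric, scale-aware
and bounded; the raw enclosed area is available as an alternative
statistic.  Group labels are then shuffled 1000 times *at the gene level*
(a gene's whole profile moves together, preserving within-gene
autocorrelation under the null; the alternative, shuffling individual
points, would destroy it and anti-conservatively narrow the null) and the
one-sided p-value per interval is $(1 + \#\{\text{perm} \ge
\text{obs}\})/(n_{\text{perm}}+1)$, so the smallest attainable p is
$1/1001$.  Intervals of one run share the two fitted curves and are highly
correlated; calibration statements should therefore average over data sets,
not over the 100 intervals of one run.

## Pseudobulk construction

Single-cell counts are pooled per cell type and sample by summing gene
counts.  Cell types are retained only with at least 1000 cells — by
default at every time point, since a single well-sampled stage cannot
rescue an otherwise empty trajectory (a global scope is the alternative
switch).  The threshold is inclusive.  Lowly expressed genes are removed by
a CPM-in-k-samples rule (CPM ≥ 1 in at least the smallest time-group's
number of samples, both configurable) — an explicit, documented
approximation to the usual expression filter.  Libraries are normalized
with RLE (median-of-ratios) size factors standardized to geometric mean 1,
which makes normalization exactly idempotent, and expression is reported as
$\log_2(\mathrm{CPM}+1)$; the log base and pseudo-count are our
documented choice.

## The simulator and what it does (not) show

`simulate_time_course()` generates the benchmark the caller is scored on:
10,000 genes, 90% nondynamic, 2.5% each monotonic / one- / two- /
three-break; 3 replicates at each of 3–11 evenly spaced time points;
NB noise around embedded mean curves; monotonic endpoint changes and
per-segment changes drawn from 0.5–2 $\log_2$FC.  Class counts are
apportioned by largest-remainder rounding, so the default composition is
exact.  Where the design leaves parameters open we chose once and exposed
them as arguments:

* baseline means log-uniform on $[20, 2000]$ — spanning the low-coverage
  tail and well-expressed genes of a typical bulk library;
* dispersion following the decreasing mean–dispersion trend
  $\varphi = 3/\mu + 0.05$, i.e. a biological CV of ~22% on top of shot
  noise, a realistic bulk RNA-seq regime;
* break locations uniform over admissible interior times, segment
  directions alternating from a random initial sign;
* segment effects rejection-sampled so every anchor (including the end
  point) sits at least half the minimum effect (0.25–0.5 $\log_2$ units)
  away from baseline: an inflection anchored *at* baseline is literally
  indistinguishable from no change, which would make the truth label
  ill-defined rather than the problem harder;
* at 3 time points, where two or more interior breaks are geometrically
  impossible, multimodal classes are generated at the feasible maximum
  (one break) — they remain dynamic, truth labels record the realized
  break count;
* nondynamic genes are exactly constant in mean — noise only.

The simulation emulates NB count noise around smooth trajectories with
exchangeable replicates.  It does not emulate batch effects, outlier
samples, unequal library sizes, correlated genes, or uneven time spacing —
so passing benchmarks demonstrates the statistical machinery under the
stated noise model, not robustness to those artefacts (preprocessing
handles the first and third separately).

Scoring uses the rank-based (Mann–Whitney) AUC of $-\log_{10}$ gene
p-values against truth labels.  The problem sizes run by the acceptance
script and the test suite are 2,000-gene scaled versions of the 10,000-gene
design with identical class fractions — composition, not size, drives the
AUC, and a fifth-size run keeps a five-course benchmark in the minutes
range on one CPU.

## Numerical and degenerate-input choices

* NB computations switch to exact Poisson below $\varphi = 10^{-12}$.
* IRLS: tolerance $10^{-9}$ on the linear predictor, 50 iterations,
  predictor clamped to $\pm 25$; non-convergence is flagged and the
  per-time means reported.
* Fisher combination floors exact zeros at $10^{-300}$.
* Two-sided bar and TimeHeatmap orderings break ties alphabetically by
  pathway name, so outputs are stable.
* All randomness (simulation, permutation) flows from explicit seed
  arguments; rerunning with the same seed is bit-identical.

## A worked example

```{r example, eval = FALSE}
sim <- simulate_time_course(n_genes = 500, n_timepoints = 7, seed = 1)
expt <- preprocess(sim$expt)
fit  <- catch_trends(expt, alpha = 0.05)
glance(fit)
tidy(fit) |> dplyr::filter(is_ddeg) |> dplyr::count(master_pattern)

sets <- read_gmt(system.file("extdata", "example_sets.gmt",
                             package = "trendcurve"))
th <- build_timeheatmap(fit, sets, top_k = 10)
autoplot(th)
```

## Known limitations

* The per-time test compares a smoothed mean to the law of a single
  baseline draw; power and conservativeness both inherit from that choice.
* Dispersion is per-gene with no information sharing across genes; at 2–3
  replicates the estimates are noisy, and the clamp plus the conservative
  tail test absorb — but do not remove — that noise.
* Patterns are assigned from fitted means at observed times only; features
  between time points are invisible by construction.
* The permutation test requires a handful of genes per group; with fewer
  than ~5 the permutation space is too small for small p-values.
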