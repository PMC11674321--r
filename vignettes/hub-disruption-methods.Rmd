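---
title: "Hub disruption in functional brain networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hub disruption in functional brain networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Highly connected regions of the brain ("hubs") are thought to be selectively
vulnerable in Alzheimer's disease. The classical way to quantify this from
resting-state functional connectivity (FC) regresses the *absolute* change in
a nodal centrality measure on the reference centrality and reads a negative
slope as hub-targeted degradation. That reading is not sound: if every node
loses the same *fraction* of its connectivity (a random attack), absolute
losses still scale with the baseline, and the slope is negative anyway.

This package implements the *normalized* hub disruption index. For a test
profile (a subject or a group mean) and a reference group mean profile
$\langle S_{ref}\rangle$, the index is the slope $\kappa$ of

$$y_i = \kappa x_i + b + \varepsilon_i,\qquad
  y_i = 100\,\frac{S_{test,i} - \langle S_{ref,i}\rangle}{\langle S_{ref,i}\rangle},\qquad
  x_i = \mathrm{Zscore}(\langle S_{ref}\rangle)_i ,$$

fit by ordinary least squares across nodes. Under a uniform proportional
loss $\kappa = 0$ exactly and the mean loss appears in $b$; only
degradation concentrated on hubs makes $\kappa < 0$, and degradation
concentrated on non-hubs makes $\kappa > 0$. The legacy index (absolute
difference $S_{test} - \langle S_{ref}\rangle$ as $y$) is retained as
`kappa_legacy()` for the contrast.

Because the cohort the method was developed on (autosomal dominant
Alzheimer's disease families, with mutation carriers staged by the Clinical
Dementia Rating, CDR) is restricted-access, the package ships a synthetic
cohort generator with planted ground truth. Every claim the package makes is
validated against that planted truth, not against any private dataset.

## Graph construction and signed centrality

FC matrices are zero-lag Pearson correlations between ROI time series,
Fisher z-transformed. Correlation magnitudes are clipped at $1 - 10^{-7}$
before `atanh`: real preprocessed data never reaches $|r| = 1$, but synthetic
or degenerate inputs can, and clipping keeps z finite without affecting any
realistic value.

Sparse graphs are built by `mst_threshold()`: a *maximum* spanning tree on
the raw z values guarantees connectedness, then remaining edges are added in
descending z until the target density is reached. Choices the literature
leaves open, fixed here:

* The tree is computed on raw (not absolute) z — correlations are
  similarities, and at the sparse densities used the strongest edges are
  positive anyway. A warning is logged if a negative edge enters a graph at
  density $\le 5\%$.
* Edge count at density $d$ is $\mathrm{round}(d\,n(n-1)/2)$ with half-up
  rounding; densities whose target falls below the $n-1$ tree edges are an
  error that states the minimum feasible density rather than a silent floor.
* Ties in edge weight are broken by ascending (row, col) index so results
  are bit-reproducible.

Nodal metrics handle signed weights with asymmetric weighting: with positive
incident sum $s^+$ and absolute negative sum $s^-$, strength is
$[s^+ - \frac{s^-}{s^+ + s^-}s^-]/(n-1)$, so negative edges are discounted
by their relative magnitude at the node and a full unthresholded matrix
still yields usable strengths. The participation coefficient and
within-module strength Z-score apply the same asymmetric combination; for
the within-module Z the combination is restricted to within-module edges (the
natural reading of "connectivity to other nodes in the module"). Degenerate
cases are defined, not errors: isolated nodes get $S = 0$ and $Pc = 0$;
singleton or zero-variance modules get $Z = 0$. All z-scoring uses the
sample (n-1) standard deviation. Strength and participation are
residualized on retained scan minutes (`residualize_metric()`, which
preserves the node means) *before* any index is computed, matching the
order in which a real pipeline removes the scan-time confound.

## Attack models

`attack_strengths()` inverts the index construction exactly: given a
reference profile and a generative slope/intercept/noise specification it
returns per-node strengths whose regression recovers the specification. This
is the strength-level (exact) model used for estimator-recovery checks.

`attack_edges()` realizes the same nodal targets through the graph: node
factors $c_i = (1 + y_i/100)/\sqrt{\overline{1 + y/100}}$ multiply every
positive edge by $c_i c_j$. The normalization by the mean retention factor
makes the mechanism exact for uniform attacks and first-order exact for
heterogeneous ones: a node's realized change is $c_i$ times the weighted
mean of its neighbors' factors, and that neighbor mean concentrates at the
global mean factor. (A plain $\sqrt{1+y_i/100}$ factor without the
normalization halves the realized slope, because the neighbor mean — not
$c_i$ itself — supplies the second factor.) The residual inaccuracy is
second-order; tests assert recovery within $0.1|\kappa_{true}| + 0.5$ and
near-monotone realized changes, not exactness. Percentage targets are
clamped to $\pm 100\%$ with a warning when $\ge 5\%$ of nodes clamp.

The taxonomy default grid uses $\kappa_{true} = -16.7$ (the most affected
stage's group estimate) for the hub-targeted regime, a uniform $-10\%$ loss
for the random regime, and $(+5.164, b = -14)$ for the non-hub regime. The
sign contrast (normalized, legacy) = $(-,-)/(0,-)/(+,\le 0)$ is guaranteed
for the first two regimes; for the non-hub regime the legacy sign depends on
the reference distribution — it is $\le 0$ when the mean-loss term dominates,
i.e. $b \lesssim -\kappa(\mu/\sigma + \gamma_1)$ with $\mu,\sigma,\gamma_1$
the mean, sd and skewness of the reference. This holds for the symmetric
references the tests draw; on strongly right-skewed references (like
hub-boosted strength distributions) the legacy non-hub slope can be slightly
positive, which we document rather than assert away.

## The synthetic cohort

`generate_template_fc()` draws a block-structured z matrix: within-module
edges $\mathcal N(0.30, 0.10^2)$, between-module $\mathcal N(0.05, 0.05^2)$
— typical magnitudes for group-average resting-state FC in z units — and
promotes a random 15% of nodes to hubs by scaling their incident edges by
1.5. With 246 nodes in 13 modules this yields a heavy-tailed strength
distribution whose 85th-percentile mask recovers the planted hubs
essentially perfectly (Jaccard ≈ 1 in the bundled checks). Subjects are the
template plus i.i.d. symmetric Gaussian edge noise (sd 0.10 z, a realistic
between-subject FC variability).

`generate_cohort()` builds the staged design: carrier groups at CDR
0 / 0.5 / ≥1 with $n = 69/32/20$ and matched non-carrier groups with
$n = 52/17/15$, the study's sample sizes. Carrier subjects receive
edge-level hub-targeted attacks with stage-dependent generative slopes
$(-5.6, -9.6, -16.7)$, intercept $-10\%$, nodal noise sd 2% — the
group-level effect sizes the cohorts are calibrated to. Covariates are drawn
uniformly over the stage-specific age/EYO ranges of the study demographics;
amyloid SUVR for carriers rises with EYO (estimated years to symptom onset)
along a logistic centered at EYO $-16.9$ so that the mean crosses the 1.42
positivity cutoff years before the connectivity effect saturates; the
cognitive composite score (CCS) falls with stage and carries an injected
positive link to the stage's hub disruption ($\beta_\kappa = 0.02$ per
$\kappa$ unit) plus family random intercepts.

Two deliberate departures from real data, and their consequences:

* **Within-group κ variance is small.** Attack strength is fixed per stage,
  so per-subject κ varies only through FC noise (sd ≈ 0.8), whereas real
  individual κ spreads an order of magnitude wider. Group tests on the
  synthetic cohort are therefore much better powered than in vivo; passing
  the ordering/ANOVA checks shows the estimator and test machinery work, not
  that real effects are this clean.
* **Sparse thresholding amplifies the generative slope.** The generative κ
  targets full-matrix strengths; measured at 5% density the group κ come out
  roughly 2–2.5× larger in magnitude (ordering and signs preserved). The
  acceptance checks therefore assert ordering, power, and recovery at the
  level where the target is defined (full-matrix strengths), and the
  reported cohort κ are understood as density-specific quantities — exactly
  as in real analyses, where κ is always quoted at its edge threshold.

No site effects or harmonization are modeled; `inject_site_effects()`
exists only to let users observe what unharmonized shifts would do, and it
warns accordingly. Requested time series are multivariate Gaussian with the
target correlation — no autocorrelation or scanner artifacts.

## Trajectories, simultaneous bands, divergence

`fit_group_smooths()` fits biomarker values as group-specific penalized
cubic B-splines of EYO (k = 10 basis functions per group by default) with
shared centered linear covariates (sex, education, optionally motion) and an
optional ridge-penalized family-intercept block; smoothing parameters (one
per group, plus the family ridge) minimize generalized cross-validation.
This is a deliberate, documented simplification of the generalized additive
mixed models used in practice, with the same estimand; it is validated by
parameter recovery on planted truths, not by matching any particular
package's output. One numerical point matters: the difference penalty is
taken as divided differences on the Greville abscissae, not plain
coefficient differences. With replicated boundary knots the Greville sites
are unevenly spaced at the ends, and a plain second-difference penalty does
not annihilate straight lines there; the divided-difference form restores
the exact linear null space, which is what makes heavily smoothed fits
unbiased for linear truths and gives the simultaneous bands their nominal
coverage.

Bands come from the Gaussian approximation $\beta \sim \mathcal N(\hat\beta,
\sigma^2 (X'X + P)^{-1})$: the multiplier is the level-quantile of the
maximal standardized deviation over the 0.1-year evaluation grid (10,000
draws by default, seed mandatory), floored at the pointwise Gaussian
quantile. The default level is 0.834 because non-overlap of two such bands
approximates a 5% pairwise test when the two standard errors are similar.

The divergence point is the smallest grid EYO from which the two group
bands are disjoint *through the right edge of the grid* ("started to have no
overlap" read as sustained separation); an interior disjoint interval that
closes again reports no divergence and sets a flag, and the alternative
first-crossing rule is available as an option. Predictions hold covariates
at their sample means. `bootstrap_divergence_compare()` resamples family
blocks within group, discards replicates where either biomarker loses its
divergence (counts reported, warning below 100 valid), and returns a
percentile interval and a fraction-based two-sided p-value.

Default generator settings for trajectory checks — divergence at EYO $-12$,
effect reaching $-20$ units at the grid edge, observation noise sd 2, family
sd 1, $n = 150$ per group — were chosen by a power calculation: with this
signal-to-noise the band-separation criterion detects the divergence with
about a one-year lag, comfortably inside the ±2-year recovery tolerance the
checks assert. Weaker effects shift the detected point later; that bias is a
property of the band-overlap definition itself, not of the estimator.

## Statistical conventions

Two-sample tests are classic pooled-variance t-tests (Welch available as an
option); multiple comparisons use Benjamini–Hochberg at $q = 0.05$; effect
sizes are Cohen's d and $\eta^2$. Control matching z-scores age and EYO
across *all* participants and assigns each control to the stage of the
nearest carrier in Euclidean distance, ties to the lower carrier index. The
cognition model is `ccs ~ kappa + age + sex + education + mean_fd +
(1 | family)` by REML, degenerating to OLS (with a note) when every family
is a singleton. Binned AUC is the rank-based (Mann–Whitney) probability
that a carrier's disruption score ($-\kappa$) exceeds a non-carrier's within
a 5-year EYO or age bin; bins missing a class are skipped with a note.

## Problem sizes and reproducibility

The bundled checks run at the full study geometry (246 nodes, 13 networks,
205 subjects) where the claim concerns the cohort machinery, and at reduced
sizes (20–60 nodes, 100-seed batches) for oracle-equivalence properties
where node count is irrelevant. Every stochastic stage takes its seed from
`derive_seed(master, stage_name)`, so a single master seed reproduces an
entire analysis bit-for-bit; `run_pipeline()` writes a manifest with the
derived seeds, configuration echo, and row counts.

## Known limitations

* The edge-level attack is first-order exact by construction; extremely
  heterogeneous targets on small graphs realize with visible second-order
  error (the tests quantify it).
* The legacy-index sign under non-hub attacks is reference-dependent (see
  above); the package documents the condition instead of claiming a
  universal sign.
* GCV can undersmooth small noisy datasets, as any GCV-based smoother can;
  the bootstrap comparison inherits that variability and reports its valid
  replicate count.
* The synthetic cohort omits site effects, scanner autocorrelation,
  realistic within-stage heterogeneity, and longitudinal structure. Passing
  its checks demonstrates correctness of the estimators on data satisfying
  the generative assumptions, not robustness to everything real data does.

## A minimal session

```{r example}
library(hubdisrupt)

parc <- default_parcellation(246, 13)
sim <- generate_cohort(parc, seed = 1)
S <- cohort_strengths(sim$fc, parc, density = 0.05)
S <- residualize_metric(S, sim$cohort$retained_minutes)
ref <- build_reference(S[sim$cohort$design_cell == "NC_match1", ], percentile = 85)
indiv <- individual_kappas(S, ref)
tapply(indiv$kappa, sim$cohort$design_cell, mean)

traj <- generate_trajectories(seed = 1)
est <- estimate_divergence(traj, seed = 2)
est$divergence$divergence_eyo
```
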