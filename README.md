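# hubdisrupt

Quantifying selective hub vulnerability in weighted functional brain
networks, with a fully synthetic, ground-truthed test bed.

## The problem

In neurodegenerative disease, the question is not just *whether* functional
connectivity (FC) declines, but *where*: do highly connected hub regions
lose proportionally more connectivity than the rest of the brain (a targeted
attack), or does every region lose the same fraction (a random attack)? The
classical "hub disruption index" — the slope of the regression of the
*absolute* centrality change on reference centrality — cannot tell these
apart: absolute losses scale with the baseline, so the slope is negative
even under uniform proportional loss.

This package implements the **normalized hub disruption index**. With a
reference group's mean nodal strength ⟨S_ref⟩ and a test profile S_test
(one subject or a group mean), it fits across nodes

    y = κ·x + b + ε,   y_i = 100 · (S_test,i − ⟨S_ref,i⟩) / ⟨S_ref,i⟩,
                       x_i = Z-score(⟨S_ref⟩)_i

Under uniform proportional loss κ = 0 (the mean loss moves to the intercept
b); κ < 0 only when hubs lose proportionally more; κ > 0 when non-hubs do.
The legacy absolute-difference index is kept alongside for the contrast.

Around the index the package provides, for researchers working with ROI
time-series or connectivity matrices:

* signed, asymmetrically weighted nodal centralities — strength,
  participation coefficient, within-module strength Z-score — on full or
  density-thresholded graphs with a maximum-spanning-tree backbone;
* strength- and edge-level attack simulators (hub-targeted / random /
  non-hub-targeted) with exact generative slopes;
* a synthetic staged cohort generator (246 ROIs, 13 networks; carrier
  groups at CDR 0/0.5/≥1 with matched controls at the published group
  sizes) with planted hubs, stage-calibrated attacks, covariates, amyloid
  status, and cognition linked to disruption;
* cohort statistics: z-space control matching, ROI-wise tests with
  Benjamini–Hochberg control, κ group tests and effect sizes, a
  mixed-model κ–cognition regression, binned AUC;
* penalized B-spline group trajectories over estimated years to onset
  (EYO) with 83.4% simultaneous confidence bands, divergence-point
  estimation, and a family-block bootstrap comparison of divergence points.

## Worked example

```r
library(hubdisrupt)

parc <- default_parcellation(246, 13)          # 246 ROIs in 13 networks
sim  <- generate_cohort(parc, seed = 1)        # staged synthetic cohort (205 subjects)

S   <- cohort_strengths(sim$fc, parc, density = 0.05)   # 5% MST-backbone graphs
S   <- residualize_metric(S, sim$cohort$retained_minutes)
ref <- build_reference(S[sim$cohort$design_cell == "NC_match1", ], percentile = 85)
sum(ref$hub_mask)
#> [1] 37

indiv <- individual_kappas(S, ref)
round(tapply(indiv$kappa, sim$cohort$design_cell, mean), 2)
#>   MC_CDR0 MC_CDR0.5   MC_CDR1 NC_match1 NC_match2 NC_match3
#>    -13.98    -22.13    -37.04      0.00     -0.14     -0.28

mc <- sim$cohort$group == "MC"
kappa_group_tests(indiv$kappa[mc], sim$cohort$design_cell[mc])$anova$F_stat
#> [1] 5191.2  # F(2, 118)

traj <- generate_trajectories(seed = 1)        # biomarker with divergence planted at EYO -12
estimate_divergence(traj, seed = 2)$divergence$divergence_eyo
#> [1] -12.1
```

Reading the output: the 85th-percentile mask flags 37 of 246 reference
nodes as hubs; mean individual κ is near 0 in every control group and
becomes increasingly negative across carrier stages (the attacked cohorts
were generated with hub-targeted slopes −5.6/−9.6/−16.7 on full-matrix
strengths; measured at 5% edge density the magnitudes are amplified ~2×,
with ordering and signs preserved — see the methods vignette). The ANOVA
confirms the stage effect, and the trajectory machinery recovers the
planted divergence at EYO −12 to about a tenth of a year in this draw.

## The analysis workflow

Numbered drivers under `analysis/` run the full study end to end and write
tables under `results/`:

1. `01_simulate_cohort.R` — staged cohort with planted hubs and attacks
2. `02_network_metrics.R` — thresholded signed centralities, scan-time
   residualization, hub identification against the planted mask
3. `03_hub_disruption.R` — group and individual κ, slope-comparison
   F-tests (df 1, 488)
4. `04_attack_taxonomy.R` — normalized-vs-legacy contrast across attack
   regimes; estimator recovery under noise
5. `05_group_statistics.R` — matching, κ tests, ROI-wise FDR tests,
   binned AUC, κ–cognition mixed model
6. `06_trajectories.R` — trajectory fits, simultaneous bands, divergence
   points, bootstrap comparison

`run_pipeline(default_config())` performs the same sweep programmatically
and writes a manifest; re-running any configuration is byte-identical.

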