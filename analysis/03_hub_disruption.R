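#!/usr/bin/env Rscript
# Stage 3: hub disruption indices across disease stages.
#
# Uses the young-control group (NC match 1) as the reference, computes the
# group-level normalized index for each remaining group, per-subject indices
# for everyone, and slope-comparison F-tests between MC stages
# (denominator df = 2*246 - 4 = 488).

library(hubdisrupt)

seed <- 1L
parc <- default_parcellation(246L, 13L)
sim <- generate_cohort(parc, seed = derive_seed(seed, "cohort"))
S <- cohort_strengths(sim$fc, parc, density = 0.05)
S <- residualize_metric(S, sim$cohort$retained_minutes)

cell <- sim$cohort$design_cell
ref <- build_reference(S[cell == "NC_match1", ], 85)

cells <- setdiff(unique(cell), "NC_match1")
group_fits <- do.call(rbind, lapply(cells, function(cl) {
  f <- kappa_normalized(colMeans(S[cell == cl, , drop = FALSE]), ref)
  data.frame(group = cl, kappa = f$kappa, intercept = f$intercept_b,
             r_squared = f$r_squared, F_stat = f$F_stat,
             df1 = f$df[1], df2 = f$df[2], p_value = f$p_value)
}))
write_result_table(group_fits, "results/kappa_group.csv")

indiv <- individual_kappas(S, ref)
indiv$design_cell <- cell
write_result_table(indiv, "results/kappa_individual.csv")

mean_profile <- function(cl) colMeans(S[cell == cl, , drop = FALSE])
pairs <- list(c("MC_CDR0", "MC_CDR0.5"), c("MC_CDR0.5", "MC_CDR1"),
              c("MC_CDR0", "MC_CDR1"))
slope_cmp <- do.call(rbind, lapply(pairs, function(pr) {
  cmp <- compare_slopes(mean_profile(pr[1]), mean_profile(pr[2]), ref)
  data.frame(group_A = pr[1], group_B = pr[2], kappa_A = cmp$kappa_A,
             kappa_B = cmp$kappa_B, F_stat = cmp$F_stat,
             df1 = cmp$df[1], df2 = cmp$df[2], p_value = cmp$p_value)
}))
write_result_table(slope_cmp, "results/kappa_slope_comparisons.csv")

cat("group-level normalized hub disruption indices:\n")
print(group_fits[, c("group", "kappa", "r_squared")], row.names = FALSE)
cat("\nslope comparisons (df2 = 488):\n")
print(slope_cmp[, c("group_A", "group_B", "F_stat", "p_value")], row.names = FALSE)
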