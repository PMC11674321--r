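test_that("seed derivation is deterministic and within integer range", {
  expect_identical(derive_seed(1, "cohort"), derive_seed(1, "cohort"))
  expect_false(derive_seed(1, "cohort") == derive_seed(2, "cohort"))
  expect_false(derive_seed(1, "a") == derive_seed(1, "b"))
  seeds <- sapply(1:50, function(m) derive_seed(m, "stage"))
  expect_true(all(seeds >= 0 & seeds < 2^31))
  expect_true(is.integer(derive_seed(999999999, "x")))
})

test_that("template generation is reproducible and plants recoverable hubs", {
  parc <- default_parcellation(246, 13)
  t1 <- generate_template_fc(parc, seed = 5)
  t2 <- generate_template_fc(parc, seed = 5)
  expect_identical(t1, t2)
  expect_equal(t1, t(t1), ignore_attr = TRUE)
  expect_equal(diag(t1), rep(0, 246))
  # planted hubs recovered by the 85th-percentile strength mask
  jacc <- sapply(1:10, function(s) {
    tpl <- generate_template_fc(parc, seed = s)
    planted <- attr(tpl, "hubs")
    mask <- ref_from_means(signed_strength(tpl))$hub_mask
    sum(mask & planted) / sum(mask | planted)
  })
  expect_gte(median(jacc), 0.9)
  expect_error(generate_template_fc(parc, within_mean = 0.05, between_mean = 0.3),
               "within_mean")
})

test_that("subject sampling is unbiased symmetric noise around the template", {
  parc <- default_parcellation(60, 6)
  tpl <- generate_template_fc(parc, seed = 2)
  expect_equal(sample_subject_fc(tpl, 0, seed = 3), tpl, ignore_attr = TRUE)
  s1 <- sample_subject_fc(tpl, 0.1, seed = 3)
  expect_identical(s1, sample_subject_fc(tpl, 0.1, seed = 3))
  expect_false(identical(s1, sample_subject_fc(tpl, 0.1, seed = 4)))
  expect_equal(s1, t(s1))
  # law of large numbers: mean of 50 subjects approaches the template
  acc <- matrix(0, 60, 60)
  for (s in 1:50) acc <- acc + sample_subject_fc(tpl, 0.1, seed = s)
  dev <- max(abs(acc / 50 - tpl))
  expect_lt(dev, 3 * 0.1 / sqrt(50) * sqrt(2 * log(60 * 59)))
})

test_that("cohort generation is bit-reproducible with coherent covariates", {
  parc <- default_parcellation(40, 4)
  design <- lapply(default_cohort_design(), function(d) { d$n <- 4L; d })
  c1 <- generate_cohort(parc, design, seed = 11)
  c2 <- generate_cohort(parc, design, seed = 11)
  expect_identical(c1$cohort, c2$cohort)
  expect_identical(c1$fc, c2$fc)
  co <- c1$cohort
  expect_identical(co$amyloid_positive, co$amyloid_suvr > 1.42)
  expect_true(all(co$cdr_stage[co$group == "NC"] == 0))
  expect_equal(nrow(co), 24)
  expect_equal(length(c1$fc), 24)
  expect_error(generate_cohort(parc, lapply(design, function(d) { d$n <- 0L; d })),
               "empty group")
})

test_that("null-attack cohorts leave MC and NC exchangeable", {
  parc <- default_parcellation(40, 4)
  design <- lapply(default_cohort_design(), function(d) {
    d$n <- 10L
    d$kappa_true <- 0
    d
  })
  # kappa_true 0 means no MC is attacked (attack only runs for MC with the
  # hub_targeted spec; emulate the null by marking everyone NC-like)
  for (i in seq_along(design)) design[[i]]$group <- "NC"
  sim <- generate_cohort(parc, design, seed = 13)
  S <- cohort_strengths(sim$fc, parc, density = 0.2)
  ref <- build_reference(S[1:10, ], 85)
  k <- individual_kappas(S, ref)$kappa
  grp_means <- tapply(k, rep(seq_along(design), each = 10), mean)
  expect_lt(max(abs(grp_means)), 2)
})

test_that("trajectory generator honors its planted mean structure", {
  d <- generate_trajectories(n_mc = 200, n_nc = 200, seed = 17)
  truth <- attr(d, "truth")
  expect_equal(truth$divergence_eyo, -12)
  # NC flat, MC equal to NC before divergence, strictly departing after
  expect_equal(truth$mc_mean(c(-25, -12)), c(0, 0))
  expect_equal(truth$nc_mean(c(-20, 0, 10)), c(0, 0, 0))
  expect_true(all(diff(truth$mc_mean(seq(-12, 10, 1))) < 0))  # effect_scale < 0
  expect_equal(truth$mc_mean(10), truth$effect_scale, tolerance = 1e-10)
  # effect 0 -> groups identically distributed
  d0 <- generate_trajectories(n_mc = 150, n_nc = 150, effect_scale = 0, seed = 18)
  mc <- d0$biomarker_value[d0$group == "MC"]
  nc <- d0$biomarker_value[d0$group == "NC"]
  expect_gt(t.test(mc, nc)$p.value, 0.01)
  expect_identical(generate_trajectories(seed = 19), generate_trajectories(seed = 19))
  expect_error(generate_trajectories(divergence_eyo = -40), "inside")
})

test_that("cognitive composite score follows the equal-weight complete-case rule", {
  expect_equal(compute_ccs(c(0, 0, 0, 0)), 0)
  expect_equal(compute_ccs(c(1, -1, 0.5, 0.5)), 0.25)
  expect_true(is.na(compute_ccs(c(1, NA, 0.5, 0.5))))
  expect_true(is.na(compute_ccs(c(1, 1, 1, 1), all_present = c(TRUE, TRUE, FALSE, TRUE))))
  m <- rbind(c(1, 1, 1, 1), c(2, 0, 1, 1))
  expect_equal(compute_ccs(m), c(1, 1))
  expect_error(compute_ccs(c(1, 2, 3)), "4 test")
})

test_that("simulate_ccs injects a recoverable kappa coefficient", {
  set.seed(23)
  n <- 112
  kappa <- rnorm(n, -8, 10)
  age <- runif(n, 20, 65); sex <- rbinom(n, 1, 0.5)
  edu <- round(runif(n, 9, 20)); fd <- runif(n, 0.04, 0.2)
  fam <- sample(sprintf("f%02d", 1:56), n, replace = TRUE)
  ccs <- simulate_ccs(kappa, age, sex, edu, fd, fam, beta_kappa = 0.02, seed = 31)
  fit <- kappa_cognition_model(data.frame(ccs = ccs, kappa = kappa, age = age,
                                          sex = sex, education = edu,
                                          mean_fd = fd, family_id = fam))
  est <- fit$coefficients[fit$coefficients$term == "kappa", ]
  expect_lt(abs(est$estimate - 0.02), 3 * est$std_error)
})

test_that("site-effect injector shifts matrices and warns about no harmonization", {
  parc <- default_parcellation(20, 4)
  tpl <- generate_template_fc(parc, seed = 3)
  fc <- list(a = tpl, b = tpl)
  expect_warning(out <- inject_site_effects(fc, c("s1", "s2"), seed = 2),
                 "harmonization")
  expect_equal(diag(out$a), rep(0, 20))
  off <- upper.tri(tpl)
  expect_equal(sd(out$a[off] - tpl[off]), 0, tolerance = 1e-12)  # constant shift
})

test_that("generated time series reproduce the target correlation structure", {
  parc <- default_parcellation(20, 4)
  tpl <- generate_template_fc(parc, seed = 4)
  ts <- generate_timeseries(tpl, frames = 4000, seed = 6)
  expect_equal(dim(ts), c(4000, 20))
  fc_hat <- compute_fc(ts)
  off <- upper.tri(tpl)
  expect_gt(cor(fc_hat[off], tpl[off]), 0.95)
})
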