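make_match_cohort <- function(mc_age, mc_eyo, mc_stage, nc_age, nc_eyo) {
  data.frame(group = rep(c("MC", "NC"), c(length(mc_age), length(nc_age))),
             age = c(mc_age, nc_age), eyo = c(mc_eyo, nc_eyo),
             cdr_stage = c(mc_stage, rep(0, length(nc_age))))
}

test_that("control matching assigns nearest carrier in z-space", {
  # single MC: every NC inherits its stage
  co <- make_match_cohort(40, -10, 0.5, c(30, 50, 45), c(-20, -1, -5))
  expect_true(all(match_controls(co) == 0.5))
  # coincident NC takes that MC's stage
  co2 <- make_match_cohort(c(30, 50), c(-20, 5), c(0, 1), 30, -20)
  expect_equal(unname(match_controls(co2)), 0)
  # three MCs on a diagonal; NC near the middle one
  co3 <- make_match_cohort(c(40, 60, 20), c(0, 20, -20), c(0, 1, 0.5),
                           40.5, -0.5)
  expect_equal(unname(match_controls(co3)), 0)
  # invariance to affine rescaling of age and EYO
  co4 <- make_match_cohort(runif(10, 20, 60), runif(10, -30, 10),
                           sample(c(0, 0.5, 1), 10, replace = TRUE),
                           runif(6, 20, 60), runif(6, -30, 10))
  a1 <- match_controls(co4)
  co4b <- co4
  co4b$age <- 3 * co4$age + 7
  co4b$eyo <- 0.5 * co4$eyo - 100
  expect_identical(a1, match_controls(co4b))
})

test_that("ROI-wise t-tests match t.test and flag a planted effect", {
  set.seed(31)
  A <- matrix(rnorm(30 * 12), 30, 12)
  B <- matrix(rnorm(30 * 12), 30, 12)
  B[, 5] <- B[, 5] + 5  # 5-sd shift at one node
  res <- roiwise_tests(A, B, q = 0.05)
  tt <- t.test(A[, 3], B[, 3], var.equal = TRUE)
  expect_equal(res$statistic[3], unname(tt$statistic), tolerance = 1e-10)
  expect_equal(res$p_value[3], tt$p.value, tolerance = 1e-10)
  expect_equal(res$df[3], 58)
  expect_true(res$fdr_flag[5])
  expect_lt(sum(res$fdr_flag[-5]), 3)
  # zero-variance node -> warned, p = 1
  A0 <- A; B0 <- B; A0[, 2] <- 1; B0[, 2] <- 1
  expect_warning(res0 <- roiwise_tests(A0, B0), "zero-variance")
  expect_equal(res0$p_value[2], 1)
  expect_error(roiwise_tests(A[1, , drop = FALSE], B[1, , drop = FALSE]),
               "at least 2")
})

test_that("BH-FDR equals the brute-force step-up oracle", {
  out <- bh_fdr(c(0.01, 0.02, 0.04), 0.05)
  expect_true(all(out$flag))  # thresholds 0.0167 / 0.0333 / 0.05
  expect_false(any(bh_fdr(1.0, 0.05)$flag))
  for (seed in 1:100) {
    set.seed(seed)
    p <- runif(sample(3:40, 1))^sample(1:3, 1)
    q <- runif(1, 0.01, 0.2)
    out <- bh_fdr(p, q)
    expect_identical(out$flag, bf_bh_flags(p, q))
    expect_equal(out$p_adjusted, bf_bh_adjust(p), tolerance = 1e-12)
    expect_true(all(diff(out$p_adjusted[order(p)]) >= -1e-12))  # monotone
  }
})

test_that("kappa group tests reproduce textbook statistics", {
  k <- c(1, 2, 3, 2, 4, 6, 5, 8, 11)
  g <- rep(c("a", "b", "c"), each = 3)
  res <- kappa_group_tests(k, g)
  # one-sample t for group a: mean 2, sd 1 -> t = 2/(1/sqrt(3))
  a <- res$one_sample[res$one_sample$group == "a", ]
  expect_equal(a$statistic, 2 / (1 / sqrt(3)), tolerance = 1e-10)
  expect_equal(a$effect_size, 2, tolerance = 1e-10)
  # ANOVA against aov's own table and eta^2 by hand
  fit <- summary(aov(k ~ factor(g)))[[1]]
  expect_equal(res$anova$F_stat, fit$`F value`[1], tolerance = 1e-10)
  expect_equal(res$anova$eta_squared,
               fit$`Sum Sq`[1] / sum(fit$`Sum Sq`), tolerance = 1e-10)
  # pairwise pooled t vs t.test
  tt <- t.test(k[g == "a"], k[g == "c"], var.equal = TRUE)
  row_ac <- res$pairwise[res$pairwise$group_A == "a" & res$pairwise$group_B == "c", ]
  expect_equal(row_ac$statistic, unname(tt$statistic), tolerance = 1e-10)
  # degenerate guards
  z <- kappa_group_tests(rep(0, 8), rep(c("x", "y"), 4))
  expect_true(all(z$one_sample$p_value == 1))
  same <- kappa_group_tests(rep(c(1, 2, 3), 4), rep(c("u", "v"), each = 6))
  expect_lt(same$anova$F_stat, 1e-20)
})

test_that("group ANOVA has power at the calibrated stage effects", {
  set.seed(41)
  rejected <- replicate(60, {
    k <- c(rnorm(69, -5.6, 10), rnorm(32, -9.6, 10), rnorm(20, -16.7, 10))
    g <- rep(c("cdr0", "cdr05", "cdr1"), c(69, 32, 20))
    kappa_group_tests(k, g)$anova$p_value < 0.05
  })
  expect_gte(mean(rejected), 0.8)
})

test_that("cognition model falls back to OLS for singleton families", {
  set.seed(51)
  n <- 40
  d <- data.frame(ccs = rnorm(n), kappa = rnorm(n), age = runif(n, 20, 60),
                  sex = rbinom(n, 1, 0.5), education = round(runif(n, 9, 20)),
                  mean_fd = runif(n), family_id = sprintf("f%02d", 1:n))
  expect_message(fit <- kappa_cognition_model(d), "OLS")
  expect_equal(fit$method, "ols")
  ols <- lm(ccs ~ kappa + age + sex + education + mean_fd, d)
  expect_equal(fit$coefficients$estimate, unname(coef(ols)), tolerance = 1e-10)
  # permuted kappa has no association
  d2 <- d; d2$family_id <- sample(sprintf("f%02d", 1:10), n, replace = TRUE)
  fit2 <- kappa_cognition_model(d2)
  expect_equal(fit2$method, "lmer")
  est <- fit2$coefficients[fit2$coefficients$term == "kappa", ]
  expect_lt(abs(est$estimate), 3 * est$std_error + 0.5)
  # rank deficiency is reported
  d3 <- d; d3$education <- d3$age
  expect_error(kappa_cognition_model(d3), "collinear")
})

test_that("rank AUC and binned AUC match concordance counting", {
  expect_equal(rank_auc(c(10, 1, 5, 0), c(TRUE, TRUE, FALSE, FALSE)), 0.75)
  expect_equal(rank_auc(c(5, 6, 1, 2), c(TRUE, TRUE, FALSE, FALSE)), 1)
  set.seed(61)
  sc <- rnorm(200)
  expect_lt(abs(rank_auc(sc, sample(c(TRUE, FALSE), 200, TRUE)) - 0.5), 0.15)
  # binned version: a bin lacking one class is skipped with a note
  scores <- c(1, 2, 3, 10, 11, 12)
  labels <- c(TRUE, FALSE, TRUE, TRUE, TRUE, TRUE)
  bins <- c(0, 1, 2, 7, 8, 9)
  out <- auc_by_bin(scores, labels, bins, width = 5)
  expect_equal(nrow(out), 2)
  expect_equal(out$auc[1], rank_auc(scores[1:3], labels[1:3]))
  expect_true(is.na(out$auc[2]))
  expect_match(out$note[2], "skipped")
})

test_that("Mann-Whitney utility agrees with wilcox.test", {
  set.seed(71)
  x <- rnorm(20); y <- rnorm(25, 0.5)
  mw <- mann_whitney(x, y)
  wt <- suppressWarnings(wilcox.test(x, y, exact = FALSE))
  expect_equal(mw$U, unname(wt$statistic))
  expect_equal(mw$p_value, wt$p.value)
})
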