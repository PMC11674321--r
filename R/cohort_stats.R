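#' Age/EYO matching of controls to carrier stage groups
#'
#' Z-scores age and estimated-years-to-onset across all participants (sample
#' sd), then assigns each non-carrier (NC) to the stage group of the
#' mutation carrier (MC) nearest in Euclidean distance in that 2-d space.
#' Ties are broken by the lower MC row index.
#'
#' @param cohort data.frame with columns `group` ("MC"/"NC"), `age`, `eyo`,
#'   and a stage label column named by `stage_col`.
#' @param stage_col name of the MC stage column (default `"cdr_stage"`).
#' @return character/numeric vector, one assigned MC stage per NC row (in NC
#'   row order), with the NC row indices as names.
#' @export
match_controls <- function(cohort, stage_col = "cdr_stage") {
  is_mc <- cohort$group == "MC"
  if (!any(is_mc) || all(is_mc)) stop("need both MC and NC participants")
  zs <- function(v) (v - mean(v)) / stats::sd(v)
  z <- cbind(zs(cohort$age), zs(cohort$eyo))
  mc_idx <- which(is_mc)
  nc_idx <- which(!is_mc)
  assigned <- sapply(nc_idx, function(i) {
    d2 <- (z[mc_idx, 1] - z[i, 1])^2 + (z[mc_idx, 2] - z[i, 2])^2
    cohort[[stage_col]][mc_idx[which.min(d2)]]  # which.min takes first = lowest index
  })
  names(assigned) <- nc_idx
  assigned
}

#' Per-node two-sample t-tests with FDR flags
#'
#' Classic pooled-variance two-sample t-test of each node's metric between
#' groups A and B, Benjamini-Hochberg adjusted at level `q`. Nodes with zero
#' pooled variance get p = 1 with a warning.
#'
#' @param metric_A,metric_B subjects x nodes matrices.
#' @param q FDR level (default 0.05).
#' @param welch use Welch's unequal-variance test instead of pooled.
#' @return data.frame per node: statistic, df, p_value, p_adjusted,
#'   effect_size (Cohen's d), fdr_flag.
#' @export
roiwise_tests <- function(metric_A, metric_B, q = 0.05, welch = FALSE) {
  metric_A <- as.matrix(metric_A); metric_B <- as.matrix(metric_B)
  if (ncol(metric_A) != ncol(metric_B)) stop("node counts differ")
  na <- nrow(metric_A); nb <- nrow(metric_B)
  if (na < 2 || nb < 2) stop("need at least 2 subjects per group")
  ma <- colMeans(metric_A); mb <- colMeans(metric_B)
  va <- apply(metric_A, 2, stats::var); vb <- apply(metric_B, 2, stats::var)
  if (welch) {
    se2 <- va / na + vb / nb
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
    stat <- (ma - mb) / sqrt(se2)
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  } else {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    stat <- (ma - mb) / sqrt(sp2 * (1 / na + 1 / nb))
    df <- rep(na + nb - 2, length(ma))
  }
  p <- 2 * stats::pt(-abs(stat), df)
  degenerate <- !is.finite(stat)
  if (any(degenerate)) {
    warning("zero-variance node(s); p set to 1 at: ",
            paste(utils::head(which(degenerate), 10), collapse = ", "))
    stat[degenerate] <- 0
    p[degenerate] <- 1
  }
  adj <- bh_fdr(p, q)
  data.frame(node = seq_along(ma), statistic = stat, df = df, p_value = p,
             p_adjusted = adj$p_adjusted,
             effect_size = (ma - mb) / sqrt(sp2),
             fdr_flag = adj$flag)
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up procedure at level `q`; returns both the rejection flags and the
#' monotone adjusted p-values.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @param q FDR level.
#' @return list with `p_adjusted` and logical `flag`.
#' @export
bh_fdr <- function(p_values, q = 0.05) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) stop("p-values outside [0, 1]")
  adj <- stats::p.adjust(p_values, method = "BH")
  list(p_adjusted = adj, flag = !is.na(adj) & adj <= q)
}

cohens_d_one <- function(x) mean(x) / stats::sd(x)

cohens_d_two <- function(x, y) {
  sp <- sqrt(((length(x) - 1) * stats::var(x) + (length(y) - 1) * stats::var(y)) /
               (length(x) + length(y) - 2))
  (mean(x) - mean(y)) / sp
}

#' Group tests of hub disruption indices
#'
#' Per group: one-sample t-test of kappa against 0 with Cohen's d. Across
#' groups: one-way ANOVA with eta-squared, and FDR-corrected pairwise
#' two-sample t-tests (pooled variance by default).
#'
#' @param kappa numeric vector of per-subject indices.
#' @param group factor/character group labels.
#' @param q FDR level for the pairwise tests.
#' @param welch use Welch pairwise tests.
#' @return list with data.frames `one_sample`, `anova`, `pairwise`.
#' @export
kappa_group_tests <- function(kappa, group, q = 0.05, welch = FALSE) {
  group <- as.character(group)
  gs <- unique(group)
  if (any(table(group) < 2)) stop("need at least 2 subjects per group")
  one <- do.call(rbind, lapply(gs, function(g) {
    x <- kappa[group == g]
    if (stats::sd(x) == 0) {
      data.frame(group = g, mean = mean(x), sd = 0, n = length(x),
                 statistic = 0, df = length(x) - 1, p_value = 1,
                 effect_size = 0)
    } else {
      tt <- stats::t.test(x, mu = 0)
      data.frame(group = g, mean = mean(x), sd = stats::sd(x), n = length(x),
                 statistic = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value, effect_size = cohens_d_one(x))
    }
  }))
  anova_df <- NULL
  pair <- NULL
  if (length(gs) >= 2) {
    fit <- stats::aov(kappa ~ factor(group))
    ss <- summary(fit)[[1]]
    anova_df <- data.frame(F_stat = ss$`F value`[1], df1 = ss$Df[1],
                           df2 = ss$Df[2], p_value = ss$`Pr(>F)`[1],
                           eta_squared = ss$`Sum Sq`[1] / sum(ss$`Sum Sq`))
    combs <- utils::combn(gs, 2)
    pair <- do.call(rbind, lapply(seq_len(ncol(combs)), function(k) {
      a <- kappa[group == combs[1, k]]; b <- kappa[group == combs[2, k]]
      tt <- stats::t.test(a, b, var.equal = !welch)
      data.frame(group_A = combs[1, k], group_B = combs[2, k],
                 statistic = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value, effect_size = cohens_d_two(a, b))
    }))
    adj <- bh_fdr(pair$p_value, q)
    pair$p_adjusted <- adj$p_adjusted
    pair$fdr_flag <- adj$flag
  }
  list(one_sample = one, anova = anova_df, pairwise = pair)
}

#' Mixed-model regression of cognition on hub disruption
#'
#' Fits `ccs ~ kappa + age + sex + education + mean_fd + (1 | family_id)` by
#' restricted maximum likelihood. When every family is a singleton (the
#' random intercept is unidentifiable) the model degenerates to ordinary
#' least squares, which is then used with a note.
#'
#' @param cohort data.frame with columns ccs, kappa, age, sex, education,
#'   mean_fd, family_id; rows with missing ccs are dropped.
#' @return list with `coefficients` (estimate, std_error, t_value, p_value
#'   per term), `method` ("lmer" or "ols"), `n`.
#' @export
kappa_cognition_model <- function(cohort) {
  d <- cohort[!is.na(cohort$ccs), , drop = FALSE]
  if (nrow(d) < 10) stop("need at least 10 subjects with CCS")
  X <- stats::model.matrix(~ kappa + age + sex + education + mean_fd, d)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    stop("rank-deficient design; collinear columns: ",
         paste(colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]], collapse = ", "))
  }
  singleton <- all(table(d$family_id) == 1)
  if (!singleton) {
    fit <- lme4::lmer(ccs ~ kappa + age + sex + education + mean_fd +
                        (1 | family_id), data = d, REML = TRUE)
    cf <- stats::coef(summary(fit))
    df_approx <- nrow(d) - ncol(X)
    out <- data.frame(term = rownames(cf), estimate = cf[, "Estimate"],
                      std_error = cf[, "Std. Error"], t_value = cf[, "t value"],
                      p_value = 2 * stats::pt(-abs(cf[, "t value"]), df_approx),
                      row.names = NULL)
    method <- "lmer"
  } else {
    message("all families are singletons; falling back to OLS")
    fit <- stats::lm(ccs ~ kappa + age + sex + education + mean_fd, data = d)
    cf <- stats::coef(summary(fit))
    out <- data.frame(term = rownames(cf), estimate = cf[, "Estimate"],
                      std_error = cf[, "Std. Error"], t_value = cf[, "t value"],
                      p_value = cf[, "Pr(>|t|)"], row.names = NULL)
    method <- "ols"
  }
  list(coefficients = out, method = method, n = nrow(d))
}

#' Rank-based AUC (Mann-Whitney) of a score for class separation
#'
#' @param scores numeric scores.
#' @param labels logical/0-1 labels (TRUE = positive class).
#' @return AUC: probability a positive outranks a negative (ties count 1/2).
#' @export
rank_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' AUC of group separation in bins of a continuous variable
#'
#' Splits subjects into fixed-width bins of `bin_var` (EYO or age) and
#' computes the rank-based AUC of `scores` for distinguishing the classes
#' within each bin. Bins missing either class are skipped with a note column.
#'
#' @param scores numeric per-subject scores (e.g. individual kappa).
#' @param labels logical/0-1 class labels (TRUE = positive, e.g. MC).
#' @param bin_var numeric binning variable.
#' @param width bin width (default 5 years).
#' @return data.frame: bin_low, bin_high, n_pos, n_neg, auc, note.
#' @export
auc_by_bin <- function(scores, labels, bin_var, width = 5) {
  labels <- as.logical(labels)
  lo <- floor(min(bin_var) / width) * width
  breaks <- seq(lo, max(bin_var) + width, by = width)
  bin <- cut(bin_var, breaks, right = FALSE)
  out <- lapply(levels(bin), function(b) {
    idx <- which(bin == b)
    k <- as.integer(factor(b, levels = levels(bin)))
    n1 <- sum(labels[idx]); n0 <- sum(!labels[idx])
    if (length(idx) == 0) return(NULL)
    if (n1 == 0 || n0 == 0) {
      data.frame(bin_low = breaks[k], bin_high = breaks[k + 1],
                 n_pos = n1, n_neg = n0, auc = NA_real_,
                 note = "one class absent; skipped")
    } else {
      data.frame(bin_low = breaks[k], bin_high = breaks[k + 1],
                 n_pos = n1, n_neg = n0,
                 auc = rank_auc(scores[idx], labels[idx]), note = "")
    }
  })
  do.call(rbind, out)
}

#' Mann-Whitney U comparison of two samples
#'
#' Utility mirroring the demographic comparisons typically reported for
#' matched cohort tables.
#'
#' @param x,y numeric samples.
#' @return list with U, p_value (normal approximation via wilcox.test).
#' @export
mann_whitney <- function(x, y) {
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE))
  list(U = unname(wt$statistic), p_value = wt$p.value)
}
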