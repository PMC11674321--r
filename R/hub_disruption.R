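#' Reference centrality profile and hub mask
#'
#' Averages a nodal metric over the subjects of a reference group, z-scores
#' the node means across nodes (sample standard deviation), and flags hubs as
#' nodes strictly above the given percentile of the mean metric.
#'
#' @param metric_matrix subjects x nodes numeric matrix of a nodal metric in
#'   the reference group.
#' @param percentile hub cutoff percentile of the node means (default 85).
#' @return Object of class `reference_profile`: list with `mean_metric`,
#'   `zscores`, `hub_mask`, `percentile`, `n_nodes`.
#' @export
build_reference <- function(metric_matrix, percentile = 85) {
  metric_matrix <- as.matrix(metric_matrix)
  if (nrow(metric_matrix) < 2) stop("need at least 2 reference subjects")
  if (ncol(metric_matrix) < 3) stop("need at least 3 nodes")
  mu <- colMeans(metric_matrix)
  sdv <- stats::sd(mu)
  if (sdv == 0) stop("reference node means have zero variance; no hub structure")
  cut <- stats::quantile(mu, percentile / 100, names = FALSE)
  structure(list(mean_metric = mu, zscores = (mu - mean(mu)) / sdv,
                 hub_mask = mu > cut, percentile = percentile,
                 n_nodes = length(mu)),
            class = "reference_profile")
}

# closed-form simple linear regression of y on x with fit statistics
ols_line <- function(y, x) {
  n <- length(y)
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  slope <- sum(xc * y) / sxx
  intercept <- mean(y) - slope * mean(x)
  fitted <- intercept + slope * x
  rss <- sum((y - fitted)^2)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - rss / tss else 0
  df2 <- n - 2L
  sigma2 <- rss / df2
  if (sigma2 > 0) {
    f <- slope^2 * sxx / sigma2
    p <- stats::pf(f, 1, df2, lower.tail = FALSE)
  } else {
    f <- if (abs(slope) > 0) Inf else 0
    p <- if (abs(slope) > 0) 0 else 1
  }
  list(slope = slope, intercept = intercept, r_squared = r2,
       F_stat = f, df = c(1L, df2), p_value = p)
}

new_hdi_fit <- function(fit, level, metric, variant) {
  structure(list(kappa = fit$slope, intercept_b = fit$intercept,
                 r_squared = fit$r_squared, F_stat = fit$F_stat,
                 df = fit$df, p_value = fit$p_value,
                 level = level, metric = metric, variant = variant),
            class = "hdi_fit")
}

#' @export
print.hdi_fit <- function(x, ...) {
  cat(sprintf("Hub disruption fit (%s, %s, metric %s)\n",
              x$variant, x$level, x$metric))
  cat(sprintf("  kappa = %.4f  intercept = %.4f  R^2 = %.4f\n",
              x$kappa, x$intercept_b, x$r_squared))
  cat(sprintf("  F(%d, %d) = %.3f, p = %.3g\n",
              x$df[1], x$df[2], x$F_stat, x$p_value))
  invisible(x)
}

#' Normalized hub disruption index
#'
#' Regresses the percentage change of a test centrality profile relative to
#' the reference mean, `y_i = 100 * (test_i - ref_i) / ref_i`, on the
#' reference z-scores `x_i`. The slope kappa is negative only when hubs lose
#' proportionally more than non-hubs (targeted attack); uniform proportional
#' loss gives kappa = 0.
#'
#' @param test_metric per-node metric vector for the test group/subject.
#' @param ref [build_reference] output.
#' @param level `"group"` or `"individual"` (recorded in the result).
#' @param metric metric label (`"S"`, `"Pc"`, `"Z"`).
#' @param eps guard: reference means at or below this are an error because the
#'   percentage change is undefined near zero.
#' @return `hdi_fit` with kappa, intercept, R^2, F(1, n-2), p.
#' @export
kappa_normalized <- function(test_metric, ref, level = "group", metric = "S",
                             eps = 1e-8) {
  stopifnot(inherits(ref, "reference_profile"))
  if (length(test_metric) != ref$n_nodes) stop("node counts differ")
  bad <- which(ref$mean_metric <= eps)
  if (length(bad) > 0) {
    stop("reference mean not positive at node(s): ",
         paste(utils::head(bad, 10), collapse = ", "),
         "; percentage change undefined")
  }
  y <- 100 * (test_metric - ref$mean_metric) / ref$mean_metric
  new_hdi_fit(ols_line(y, ref$zscores), level, metric, "normalized")
}

#' Legacy (absolute-difference) hub disruption index
#'
#' The historical formulation: the raw difference `test_i - ref_i` regressed
#' on the reference z-scores. Because absolute losses scale with the
#' reference magnitude, this index is negative even under uniform
#' proportional (random-attack) degradation.
#'
#' @inheritParams kappa_normalized
#' @return `hdi_fit` with `variant = "legacy"`.
#' @export
kappa_legacy <- function(test_metric, ref, level = "group", metric = "S") {
  stopifnot(inherits(ref, "reference_profile"))
  if (length(test_metric) != ref$n_nodes) stop("node counts differ")
  y <- test_metric - ref$mean_metric
  new_hdi_fit(ols_line(y, ref$zscores), level, metric, "legacy")
}

#' Per-subject hub disruption indices against a shared reference
#'
#' @param metric_matrix subjects x nodes matrix of the test group's metric.
#' @param ref [build_reference] output (same reference x for every subject).
#' @param metric metric label.
#' @return data.frame with one row per subject: subject_id, kappa, intercept,
#'   r_squared, F, df1, df2, p.
#' @export
individual_kappas <- function(metric_matrix, ref, metric = "S") {
  metric_matrix <- as.matrix(metric_matrix)
  ids <- rownames(metric_matrix)
  if (is.null(ids)) ids <- paste0("subj_", seq_len(nrow(metric_matrix)))
  fits <- lapply(seq_len(nrow(metric_matrix)), function(s) {
    kappa_normalized(metric_matrix[s, ], ref, level = "individual",
                     metric = metric)
  })
  data.frame(subject_id = ids,
             kappa = vapply(fits, `[[`, numeric(1), "kappa"),
             intercept = vapply(fits, `[[`, numeric(1), "intercept_b"),
             r_squared = vapply(fits, `[[`, numeric(1), "r_squared"),
             F_stat = vapply(fits, `[[`, numeric(1), "F_stat"),
             df1 = 1L, df2 = ref$n_nodes - 2L,
             p_value = vapply(fits, `[[`, numeric(1), "p_value"),
             stringsAsFactors = FALSE)
}

#' Compare two hub disruption slopes (interaction F-test)
#'
#' Stacks the node-level percentage changes of two test profiles against the
#' shared reference z-scores and tests the slope difference via the
#' group-by-x interaction in `y ~ x * group`. With two n-node profiles the
#' denominator degrees of freedom are `2n - 4` (488 for 246 nodes).
#'
#' @param test_A,test_B per-node metric vectors.
#' @param ref [build_reference] output.
#' @return list with kappa_A, kappa_B, F_stat, df, p_value.
#' @export
compare_slopes <- function(test_A, test_B, ref) {
  fa <- kappa_normalized(test_A, ref)
  fb <- kappa_normalized(test_B, ref)
  x <- ref$zscores
  y <- c(100 * (test_A - ref$mean_metric) / ref$mean_metric,
         100 * (test_B - ref$mean_metric) / ref$mean_metric)
  g <- rep(c(0, 1), each = ref$n_nodes)
  xx <- c(x, x)
  fit <- stats::lm(y ~ xx * g)
  df2 <- fit$df.residual
  est <- stats::coef(fit)[["xx:g"]]
  sigma2 <- sum(stats::residuals(fit)^2) / df2
  if (sigma2 > 0) {
    tv <- stats::coef(summary(fit))["xx:g", "t value"]
    f <- tv^2
    p <- stats::pf(f, 1, df2, lower.tail = FALSE)
  } else {
    # noise-free constructions: slopes either identical or exactly different
    f <- if (abs(est) > 1e-10) Inf else 0
    p <- if (abs(est) > 1e-10) 0 else 1
  }
  list(kappa_A = fa$kappa, kappa_B = fb$kappa, F_stat = f,
       df = c(1L, df2), p_value = p)
}
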