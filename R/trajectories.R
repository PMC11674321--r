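# cubic B-spline design with equally spaced interior knots over a fixed range
spline_knots <- function(k, range_x) {
  inner <- seq(range_x[1], range_x[2], length.out = k - 2)
  c(rep(range_x[1], 3), inner, rep(range_x[2], 3))
}

bspline_design <- function(x, k, range_x) {
  if (k < 4) stop("need at least k = 4 basis functions for cubic splines")
  splines::splineDesign(spline_knots(k, range_x), x, ord = 4, outer.ok = TRUE)
}

# difference penalty as divided differences on the Greville abscissae: its
# null space contains polynomials of degree < order exactly, including at the
# replicated boundary knots where plain index differences do not
difference_penalty <- function(k, range_x, order = 2) {
  kn <- spline_knots(k, range_x)
  xi <- (kn[2:(k + 1)] + kn[3:(k + 2)] + kn[4:(k + 3)]) / 3  # Greville sites
  D <- diag(k)
  for (o in seq_len(order)) {
    m <- nrow(D)
    D <- (D[-1, , drop = FALSE] - D[-m, , drop = FALSE]) /
      (xi[(o + 1):k] - xi[1:(k - o)])
  }
  crossprod(D)
}

#' Penalized group-wise smooth trajectories over EYO
#'
#' Fits biomarker values as group-specific penalized cubic B-spline functions
#' of estimated-years-to-onset (EYO) with shared linear covariates and an
#' optional ridge-penalized family-intercept block:
#' `y = B_g(eyo) beta_g + covariates gamma + family + error`. Spline blocks
#' carry a difference penalty of order `penalty_order`; smoothing parameters
#' (one per group, plus the family ridge) are selected by generalized
#' cross-validation. The family block is dropped automatically when every
#' family is a singleton.
#'
#' @param data data.frame with columns group ("MC"/"NC"), eyo,
#'   biomarker_value, family_id, and any requested covariates.
#' @param k number of B-spline basis functions per group (default 10).
#' @param penalty_order difference-penalty order (default 2: deviations from
#'   a straight line are penalized).
#' @param covariates covariate column names entered as centered linear terms.
#' @param lambda_grid GCV grid for the two spline smoothing parameters.
#' @param family_lambda_grid GCV grid for the family ridge penalty.
#' @return object of class `trajectory_fit`: coefficients, Bayesian-type
#'   covariance `V = sigma2 * (X'X + P)^-1`, sigma2, edf, selected lambdas,
#'   basis/knot info, covariate means, group labels, data ranges.
#' @export
fit_group_smooths <- function(data, k = 10, penalty_order = 2,
                              covariates = c("sex", "education"),
                              lambda_grid = 10^seq(-4, 5, length.out = 10),
                              family_lambda_grid = c(1, 10, 100)) {
  groups <- c("MC", "NC")
  if (!all(data$group %in% groups)) stop("group must be 'MC' or 'NC'")
  if (any(table(data$group) < 20)) stop("need at least 20 observations per group")
  if (length(unique(data$eyo)) <= k) {
    stop("k exceeds the number of unique EYO values; use a smaller k")
  }
  if (stats::sd(data$eyo) == 0) stop("EYO has no spread")
  n <- nrow(data)
  rng <- range(data$eyo)
  B <- bspline_design(data$eyo, k, rng)
  Xg <- lapply(groups, function(g) B * (data$group == g))
  cov_means <- vapply(covariates, function(cn) mean(data[[cn]]), numeric(1))
  Xc <- if (length(covariates) > 0) {
    sweep(as.matrix(data[covariates]), 2, cov_means)
  } else NULL
  fam_levels <- NULL
  Xf <- NULL
  use_family <- !is.null(data$family_id) && any(table(data$family_id) >= 2)
  if (use_family) {
    fam_levels <- sort(unique(data$family_id))
    Xf <- outer(data$family_id, fam_levels, "==") * 1
  }
  X <- do.call(cbind, c(Xg, list(Xc), list(Xf)))
  idx_g1 <- seq_len(k)
  idx_g2 <- k + seq_len(k)
  p <- ncol(X)
  Pk <- difference_penalty(k, rng, penalty_order)
  XtX <- crossprod(X)
  Xty <- crossprod(X, data$biomarker_value)
  yty <- sum(data$biomarker_value^2)
  f_grid <- if (use_family) family_lambda_grid else 1
  best <- NULL
  for (l1 in lambda_grid) for (l2 in lambda_grid) for (lf in f_grid) {
    P <- matrix(0, p, p)
    P[idx_g1, idx_g1] <- l1 * Pk
    P[idx_g2, idx_g2] <- l2 * Pk
    if (use_family) {
      idx_f <- (p - length(fam_levels) + 1):p
      P[cbind(idx_f, idx_f)] <- lf
    }
    A <- XtX + P
    R <- tryCatch(chol(A), error = function(e) NULL)
    if (is.null(R)) next
    Ainv <- chol2inv(R)
    beta <- Ainv %*% Xty
    edf <- sum(Ainv * XtX)  # tr(A^-1 XtX), XtX symmetric
    rss <- yty - 2 * sum(beta * Xty) + sum(beta * (XtX %*% beta))
    rss <- max(rss, 0)
    gcv <- n * rss / (n - edf)^2
    if (is.null(best) || gcv < best$gcv) {
      best <- list(gcv = gcv, beta = drop(beta), P = P, edf = edf, rss = rss,
                   lambdas = c(l1, l2), family_lambda = if (use_family) lf else NA)
    }
  }
  A <- XtX + best$P
  sigma2 <- best$rss / max(n - best$edf, 1)
  V <- sigma2 * solve(A)
  V <- (V + t(V)) / 2
  structure(list(beta = best$beta, V = V, sigma2 = sigma2, edf = best$edf,
                 gcv = best$gcv, lambdas = best$lambdas,
                 family_lambda = best$family_lambda,
                 k = k, penalty_order = penalty_order, range_eyo = rng,
                 groups = groups, idx = list(MC = idx_g1, NC = idx_g2),
                 covariates = covariates, cov_means = cov_means,
                 fam_levels = fam_levels, n = n),
            class = "trajectory_fit")
}

# linear functionals evaluating a group's curve on a grid (covariates held at
# their sample means, family intercept at 0)
group_contrast <- function(fit, group, grid) {
  p <- length(fit$beta)
  Bg <- bspline_design(grid, fit$k, fit$range_eyo)
  C <- matrix(0, length(grid), p)
  C[, fit$idx[[group]]] <- Bg
  C
}

#' Predicted group curves on an EYO grid
#'
#' @param fit [fit_group_smooths] output.
#' @param grid_step grid spacing in years (default 0.1).
#' @return data.frame: eyo, group, fit, se.
#' @export
predict_curves <- function(fit, grid_step = 0.1) {
  grid <- seq(fit$range_eyo[1], fit$range_eyo[2], by = grid_step)
  out <- lapply(fit$groups, function(g) {
    C <- group_contrast(fit, g, grid)
    mu <- drop(C %*% fit$beta)
    se <- sqrt(pmax(rowSums((C %*% fit$V) * C), 0))
    data.frame(eyo = grid, group = g, fit = mu, se = se)
  })
  do.call(rbind, out)
}

#' Simultaneous confidence bands for the group curves
#'
#' Draws coefficient vectors from the Gaussian approximation
#' `N(beta_hat, V)`, computes for each group the `level`-quantile of the
#' maximal standardized deviation over the grid, and widens the pointwise
#' standard-error band by that multiplier (never below the pointwise Gaussian
#' quantile). The default level 0.834 makes non-overlap of two group bands
#' an approximate 5% pairwise test when standard errors are similar.
#'
#' @param fit [fit_group_smooths] output.
#' @param level simultaneous coverage level (default 0.834).
#' @param n_draws Gaussian draws (default 10000).
#' @param seed integer seed (mandatory for reproducible bands).
#' @param grid_step grid spacing in years.
#' @return data.frame: eyo, group, fit, se, lower, upper, crit.
#' @export
simultaneous_band <- function(fit, level = 0.834, n_draws = 10000, seed = 1L,
                              grid_step = 0.1) {
  ev <- eigen(fit$V, symmetric = TRUE)
  if (min(ev$values) < -1e-8 * max(abs(ev$values))) {
    stop("coefficient covariance is not positive semidefinite")
  }
  L <- ev$vectors %*% (sqrt(pmax(ev$values, 0)) * t(ev$vectors))
  grid <- seq(fit$range_eyo[1], fit$range_eyo[2], by = grid_step)
  p <- length(fit$beta)
  Z <- with_seed(seed, matrix(stats::rnorm(p * n_draws), p, n_draws))
  dev <- L %*% Z  # p x n_draws coefficient deviations
  out <- lapply(fit$groups, function(g) {
    C <- group_contrast(fit, g, grid)
    mu <- drop(C %*% fit$beta)
    se <- sqrt(pmax(rowSums((C %*% fit$V) * C), 0))
    Dg <- C %*% dev  # grid x n_draws
    mx <- apply(abs(Dg) / ifelse(se > 0, se, 1), 2, max)
    crit <- stats::quantile(mx, level, names = FALSE)
    crit <- max(crit, stats::qnorm((1 + level) / 2))
    data.frame(eyo = grid, group = g, fit = mu, se = se,
               lower = mu - crit * se, upper = mu + crit * se, crit = crit)
  })
  do.call(rbind, out)
}

#' Divergence point of two group bands
#'
#' Scans the common EYO grid for the smallest value from which the MC and NC
#' simultaneous bands are disjoint at every later grid point through the
#' right edge (`rule = "sustained"`, the default reading of "started to have
#' no overlap"), or simply the first disjoint grid point
#' (`rule = "first"`).
#'
#' @param bands output of [simultaneous_band()].
#' @param rule `"sustained"` or `"first"`.
#' @return list with `divergence_eyo` (NA if none), `rule`,
#'   `interior_interval` (TRUE when disjointness occurs but is not sustained
#'   to the right edge), `grid_range`.
#' @export
divergence_point <- function(bands, rule = c("sustained", "first")) {
  rule <- match.arg(rule)
  mc <- bands[bands$group == "MC", ]
  nc <- bands[bands$group == "NC", ]
  if (!isTRUE(all.equal(mc$eyo, nc$eyo))) stop("bands must share a grid")
  disjoint <- mc$lower > nc$upper | nc$lower > mc$upper
  m <- length(disjoint)
  res <- list(divergence_eyo = NA_real_, rule = rule,
              interior_interval = FALSE,
              grid_range = range(mc$eyo))
  if (!any(disjoint)) return(res)
  if (rule == "first") {
    res$divergence_eyo <- mc$eyo[which(disjoint)[1]]
    return(res)
  }
  # smallest index from which disjointness holds through the right edge
  sustained_from <- rev(cumprod(rev(disjoint))) > 0
  if (sustained_from[m]) {
    i <- which(sustained_from)[1]
    res$divergence_eyo <- mc$eyo[i]
    res$interior_interval <- i > 1 && any(disjoint[1:(i - 1)])
  } else {
    # disjoint somewhere but overlap returns before the right edge
    res$interior_interval <- TRUE
  }
  res
}

#' One-call divergence estimation for a trajectory dataset
#'
#' Fits the group smooths, computes simultaneous bands, and locates the
#' divergence point.
#'
#' @inheritParams fit_group_smooths
#' @inheritParams simultaneous_band
#' @param rule divergence rule, see [divergence_point()].
#' @param ... passed to [fit_group_smooths()] (e.g. smaller lambda grids).
#' @return list with `fit`, `bands`, `divergence` (see [divergence_point()]).
#' @export
estimate_divergence <- function(data, k = 10, covariates = c("sex", "education"),
                                level = 0.834, n_draws = 10000, seed = 1L,
                                grid_step = 0.1, rule = "sustained", ...) {
  fit <- fit_group_smooths(data, k = k, covariates = covariates, ...)
  bands <- simultaneous_band(fit, level = level, n_draws = n_draws,
                             seed = seed, grid_step = grid_step)
  list(fit = fit, bands = bands, divergence = divergence_point(bands, rule))
}

#' Bootstrap comparison of divergence points across two biomarkers
#'
#' Resamples subjects (family blocks jointly, within group) with replacement
#' in each dataset, re-estimates both divergence points per replicate,
#' discards replicates where either biomarker has no valid divergence, and
#' summarizes the distribution of the difference (A minus B).
#'
#' @param dataset_A,dataset_B trajectory data.frames (see
#'   [generate_trajectories()]); both must yield a divergence on the
#'   original fit.
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed integer seed.
#' @param k,covariates,level,n_draws,grid_step,... passed to the
#'   per-replicate fits (`n_draws` defaults lower than for a single fit).
#' @return list: observed_diff, p_value (fraction-based two-sided),
#'   ci_95 (percentile), n_valid, n_boot, diffs, low_confidence flag.
#' @export
bootstrap_divergence_compare <- function(dataset_A, dataset_B, n_boot = 1000,
                                         seed = 1L, k = 10,
                                         covariates = c("sex", "education"),
                                         level = 0.834, n_draws = 2000,
                                         grid_step = 0.1, ...) {
  est <- function(d, s) {
    r <- tryCatch(estimate_divergence(d, k = k, covariates = covariates,
                                      level = level, n_draws = n_draws,
                                      seed = s, grid_step = grid_step, ...),
                  error = function(e) NULL)
    if (is.null(r)) NA_real_ else r$divergence$divergence_eyo
  }
  dA <- est(dataset_A, derive_seed(seed, "orig_A"))
  dB <- est(dataset_B, derive_seed(seed, "orig_B"))
  if (is.na(dA) || is.na(dB)) {
    stop("both datasets must yield a divergence point on the original fit")
  }
  resample <- function(d, s) {
    with_seed(s, {
      pieces <- lapply(c("MC", "NC"), function(g) {
        dg <- d[d$group == g, , drop = FALSE]
        fams <- unique(dg$family_id)
        pick <- sample(fams, length(fams), replace = TRUE)
        do.call(rbind, lapply(seq_along(pick), function(j) {
          blk <- dg[dg$family_id == pick[j], , drop = FALSE]
          blk$family_id <- paste0(blk$family_id, "_b", j)
          blk
        }))
      })
      do.call(rbind, pieces)
    })
  }
  diffs <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    da <- est(resample(dataset_A, derive_seed(seed, paste0("A", b))),
              derive_seed(seed, paste0("bandA", b)))
    db <- est(resample(dataset_B, derive_seed(seed, paste0("B", b))),
              derive_seed(seed, paste0("bandB", b)))
    diffs[b] <- da - db
  }
  valid <- diffs[!is.na(diffs)]
  low_conf <- length(valid) < 100
  if (low_conf) warning("fewer than 100 valid bootstrap replicates; ",
                        "results are low-confidence")
  p <- min(1, 2 * min(mean(valid <= 0), mean(valid >= 0)))
  list(observed_diff = dA - dB, divergence_A = dA, divergence_B = dB,
       p_value = p,
       ci_95 = stats::quantile(valid, c(0.025, 0.975), names = FALSE),
       n_valid = length(valid), n_boot = n_boot, diffs = diffs,
       low_confidence = low_conf)
}
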