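#' Deterministic sub-seed from a master seed and a stage name
#'
#' Every stochastic stage of a run derives its seed from the single master
#' seed and its stage label, so one integer reproduces an entire analysis.
#' The result is always a valid 31-bit R integer seed.
#'
#' @param master master integer seed.
#' @param stage character stage label.
#' @return integer seed in `[0, 2^31)`.
#' @export
derive_seed <- function(master, stage) {
  s <- as.double(master %% 2147483647)
  for (ch in utf8ToInt(stage)) s <- (s * 31 + ch) %% 2147483647
  as.integer(s)
}

with_seed <- function(seed, expr) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  expr
}

#' Modular template connectivity matrix with planted hubs
#'
#' Generates a block-structured Fisher-z matrix: within-module edges around
#' `within_mean`, between-module edges around `between_mean`, and a random
#' fraction of nodes promoted to hubs by scaling their incident edges by
#' `hub_boost`. This emulates the modular, heavy-tailed-strength organization
#' of group-average resting-state connectivity.
#'
#' @param parc [parcellation].
#' @param within_mean,between_mean mean z of within-/between-module edges
#'   (must satisfy `within_mean > between_mean > 0`).
#' @param within_sd,between_sd edge-level sd of the two blocks.
#' @param hub_fraction fraction of nodes planted as hubs, in (0, 0.5).
#' @param hub_boost multiplicative boost of hub incident edges (1 = no hubs).
#' @param seed integer seed.
#' @return connectivity matrix with attribute `"hubs"` (logical planted mask).
#' @export
generate_template_fc <- function(parc, within_mean = 0.30, between_mean = 0.05,
                                 within_sd = 0.10, between_sd = 0.05,
                                 hub_fraction = 0.15, hub_boost = 1.5,
                                 seed = 1L) {
  if (!(within_mean > between_mean && between_mean > 0)) {
    stop("need within_mean > between_mean > 0")
  }
  if (hub_fraction <= 0 || hub_fraction >= 0.5) stop("hub_fraction must be in (0, 0.5)")
  if (hub_boost < 1) stop("hub_boost must be >= 1")
  n <- nrow(parc)
  mod <- parc$module_id
  with_seed(seed, {
    same <- outer(mod, mod, "==")
    mu <- ifelse(same, within_mean, between_mean)
    sdv <- ifelse(same, within_sd, between_sd)
    z <- matrix(0, n, n)
    ut <- upper.tri(z)
    z[ut] <- stats::rnorm(sum(ut), mu[ut], sdv[ut])
    z <- z + t(z)
    hubs <- logical(n)
    hubs[sample.int(n, max(1L, round(hub_fraction * n)))] <- TRUE
    boost <- ifelse(hubs, hub_boost, 1)
    z <- z * outer(boost, boost)
    diag(z) <- 0
    z <- connectivity_matrix(z)
    attr(z, "hubs") <- hubs
    z
  })
}

#' Subject-level connectivity: template plus symmetric noise
#'
#' @param template connectivity matrix.
#' @param subject_noise_sd sd of i.i.d. Gaussian noise added to each
#'   off-diagonal z entry (symmetrically).
#' @param seed integer seed.
#' @return connectivity matrix.
#' @export
sample_subject_fc <- function(template, subject_noise_sd = 0.10, seed = 1L) {
  if (subject_noise_sd < 0) stop("subject_noise_sd must be >= 0")
  n <- nrow(template)
  with_seed(seed, {
    e <- matrix(0, n, n)
    ut <- upper.tri(e)
    e[ut] <- stats::rnorm(n * (n - 1) / 2, 0, subject_noise_sd)
    # symmetric by construction; skip the full validator in this hot path
    out <- template + e + t(e)
    diag(out) <- 0
    attr(out, "hubs") <- NULL
    out
  })
}

# reference profile straight from a template's full-matrix strengths; the
# generative x for attack simulations
template_reference <- function(template, percentile = 85) {
  s <- signed_strength(template)
  sdv <- stats::sd(s)
  if (sdv == 0) stop("template strengths have zero variance")
  cut <- stats::quantile(s, percentile / 100, names = FALSE)
  structure(list(mean_metric = s, zscores = (s - mean(s)) / sdv,
                 hub_mask = s > cut, percentile = percentile,
                 n_nodes = length(s)),
            class = "reference_profile")
}

#' Default staged cohort design
#'
#' Mutation-carrier (MC) groups at Clinical Dementia Rating (CDR) stages
#' 0 / 0.5 / >=1 with matched non-carrier (NC) groups, at the study's group
#' sizes (69/32/20 MC, 52/17/15 NC). Stage-dependent edge-level hub-targeted
#' attacks use generative slopes (-5.6, -9.6, -16.7) with intercept -10% and
#' 2% nodal noise, the group-level effect sizes the cohorts are calibrated
#' to. Age/EYO ranges follow the staged study demographics; stage-level
#' cognitive composite score (CCS) means fall with severity.
#'
#' @return list of per-group design lists.
#' @export
default_cohort_design <- function() {
  list(
    list(name = "MC_CDR0",   group = "MC", cdr_stage = 0,   n = 69L,
         kappa_true = -5.6, age_range = c(18, 53), eyo_range = c(-36, -0.5),
         ccs_mean = 0),
    list(name = "MC_CDR0.5", group = "MC", cdr_stage = 0.5, n = 32L,
         kappa_true = -9.6, age_range = c(29, 66), eyo_range = c(-14.2, 10.4),
         ccs_mean = -1.5),
    list(name = "MC_CDR1",   group = "MC", cdr_stage = 1,   n = 20L,
         kappa_true = -16.7, age_range = c(36, 67), eyo_range = c(-1.8, 14.9),
         ccs_mean = -2.7),
    list(name = "NC_match1", group = "NC", cdr_stage = 0, n = 52L,
         kappa_true = 0, age_range = c(21, 53), eyo_range = c(-31.5, -0.8),
         ccs_mean = 0),
    list(name = "NC_match2", group = "NC", cdr_stage = 0, n = 17L,
         kappa_true = 0, age_range = c(29, 63), eyo_range = c(-14.5, 8.9),
         ccs_mean = 0),
    list(name = "NC_match3", group = "NC", cdr_stage = 0, n = 15L,
         kappa_true = 0, age_range = c(36, 70), eyo_range = c(-3.3, 20.8),
         ccs_mean = 0)
  )
}

#' Simulate cognitive composite scores linked to hub disruption
#'
#' CCS is generated as a linear function of the subject's hub disruption
#' index plus demographic effects, a family random intercept, and noise, so
#' that downstream mixed-model regression can recover the injected
#' kappa coefficient.
#'
#' @param kappa per-subject hub disruption index values.
#' @param age,sex,education,mean_fd covariates (sex coded 0/1).
#' @param family_id family labels (shared intercepts).
#' @param beta_kappa injected coefficient of kappa (default 0.02).
#' @param beta_age,beta_sex,beta_education,beta_fd fixed covariate effects.
#' @param family_sd sd of family random intercepts.
#' @param noise_sd residual sd.
#' @param intercept grand intercept.
#' @param seed integer seed.
#' @return numeric CCS vector.
#' @export
simulate_ccs <- function(kappa, age, sex, education, mean_fd, family_id,
                         beta_kappa = 0.02, beta_age = -0.01, beta_sex = 0.1,
                         beta_education = 0.05, beta_fd = -2,
                         family_sd = 0.2, noise_sd = 0.3, intercept = 0,
                         seed = 1L) {
  n <- length(kappa)
  with_seed(seed, {
    fams <- unique(family_id)
    fam_eff <- stats::rnorm(length(fams), 0, family_sd)
    names(fam_eff) <- fams
    intercept + beta_kappa * kappa + beta_age * age + beta_sex * sex +
      beta_education * education + beta_fd * mean_fd +
      fam_eff[as.character(family_id)] + stats::rnorm(n, 0, noise_sd)
  })
}

#' Generate a staged synthetic cohort
#'
#' Builds a hub-bearing template, draws per-subject connectivity (template +
#' noise), applies stage-dependent edge-level hub-targeted attacks to MC
#' subjects, and fills a covariate table (age, EYO, sex, education, motion,
#' retained scan minutes, family, site, amyloid SUVR/positivity, CCS).
#' Amyloid SUVR for carriers rises with EYO and crosses the 1.42 positivity
#' cutoff several years before the connectivity effect saturates; CCS is
#' linked positively to the subject's generative hub disruption.
#'
#' @param parc [parcellation].
#' @param design list of group designs, see [default_cohort_design()].
#' @param seed master integer seed; all internal draws derive from it.
#' @param subject_noise_sd per-subject connectivity noise (z units).
#' @param attack_noise_sd nodal percentage noise of the attacks.
#' @param ... passed to [generate_template_fc()].
#' @return list with `fc` (named list of connectivity matrices), `cohort`
#'   (data.frame), `template`, `reference` (generative reference profile).
#' @export
generate_cohort <- function(parc, design = default_cohort_design(), seed = 1L,
                            subject_noise_sd = 0.10, attack_noise_sd = 2, ...) {
  if (any(vapply(design, function(d) d$n, numeric(1)) < 1)) stop("empty group")
  template <- generate_template_fc(parc, seed = derive_seed(seed, "template"), ...)
  ref <- template_reference(template)
  fc <- list()
  rows <- list()
  idx <- 0L
  for (d in design) {
    for (s in seq_len(d$n)) {
      idx <- idx + 1L
      sid <- sprintf("sub_%03d", idx)
      sfc <- sample_subject_fc(template, subject_noise_sd,
                               seed = derive_seed(seed, paste0("fc_", sid)))
      kappa_gen <- 0
      if (d$group == "MC") {
        sp <- attack_spec("hub_targeted", kappa_true = d$kappa_true,
                          intercept_true = -10, noise_sd = attack_noise_sd,
                          level = "edge",
                          seed = derive_seed(seed, paste0("attack_", sid)))
        sfc <- attack_edges(sfc, ref, sp, validate = FALSE)
        kappa_gen <- d$kappa_true
      }
      fc[[sid]] <- sfc
      cov_seed <- derive_seed(seed, paste0("cov_", sid))
      rows[[idx]] <- with_seed(cov_seed, {
        age <- stats::runif(1, d$age_range[1], d$age_range[2])
        eyo <- stats::runif(1, d$eyo_range[1], d$eyo_range[2])
        sex <- stats::rbinom(1, 1, 0.5)
        edu <- round(stats::runif(1, 9, 20))
        fd <- stats::runif(1, 0.04, 0.20)
        mins <- stats::runif(1, 3.2, 10)
        suvr <- if (d$group == "MC") {
          1.0 + 0.8 * stats::plogis((eyo + 16.9) / 3) + stats::rnorm(1, 0, 0.15)
        } else {
          stats::rnorm(1, 1.0, 0.10)
        }
        data.frame(subject_id = sid, group = d$group, design_cell = d$name,
                   cdr_stage = d$cdr_stage, age = age, eyo = eyo,
                   sex = sex, education = edu, mean_fd = fd,
                   retained_minutes = mins,
                   family_id = NA_character_, site_id = "site_1",
                   amyloid_suvr = suvr, amyloid_positive = suvr > 1.42,
                   kappa_gen = kappa_gen,
                   stringsAsFactors = FALSE)
      })
    }
  }
  cohort <- do.call(rbind, rows)
  n_total <- nrow(cohort)
  cohort$family_id <- with_seed(derive_seed(seed, "families"), {
    sprintf("fam_%03d", sample.int(max(2L, round(n_total / 2)), n_total,
                                   replace = TRUE))
  })
  # stage-level CCS mean plus a positive link to the subject's kappa deviation
  ccs_mean <- unlist(lapply(design, function(d) rep(d$ccs_mean, d$n)))
  kappa_true_vec <- unlist(lapply(design, function(d) rep(d$kappa_true, d$n)))
  cohort$ccs <- ccs_mean + simulate_ccs(
    kappa_true_vec,
    cohort$age - mean(cohort$age), cohort$sex,
    cohort$education - mean(cohort$education), cohort$mean_fd,
    cohort$family_id, seed = derive_seed(seed, "ccs"))
  list(fc = fc, cohort = cohort, template = template, reference = ref)
}

#' Cognitive composite score from four normalized test scores
#'
#' Equal-weight mean of the four test z-scores; missing whenever any of the
#' four tests is absent (complete-case rule).
#'
#' @param test_zscores numeric vector of 4 scores, or an n x 4 matrix.
#' @param all_present optional logical (vector/matrix) marking which tests
#'   were completed; any `FALSE` renders the score missing.
#' @return CCS value(s); `NA` where incomplete.
#' @export
compute_ccs <- function(test_zscores, all_present = NULL) {
  if (is.matrix(test_zscores) || is.data.frame(test_zscores)) {
    m <- as.matrix(test_zscores)
    if (ncol(m) != 4) stop("expected 4 test scores per subject")
    out <- rowMeans(m)
    if (!is.null(all_present)) out[!apply(all_present, 1, all)] <- NA_real_
    out
  } else {
    if (length(test_zscores) != 4) stop("expected 4 test scores")
    if (!is.null(all_present) && !all(all_present)) return(NA_real_)
    if (anyNA(test_zscores)) return(NA_real_)
    mean(test_zscores)
  }
}

#' EYO-indexed biomarker trajectories with a planted divergence point
#'
#' Non-carrier expectation is flat in estimated-years-to-onset (EYO); the
#' carrier expectation equals it up to `divergence_eyo` and then departs
#' along a half-sigmoid reaching `effect_scale` at the right edge of
#' `eyo_range`. Family random intercepts and observation noise are added, and
#' small sex/education effects make the covariate adjustment non-trivial.
#'
#' @param n_mc,n_nc subjects per group.
#' @param eyo_range numeric length-2 range of EYO (years).
#' @param divergence_eyo planted divergence (years), inside `eyo_range`.
#' @param effect_scale biomarker change at the right edge (same units as the
#'   biomarker; sign free).
#' @param family_sd sd of family random intercepts.
#' @param noise_sd observation noise sd.
#' @param seed integer seed.
#' @return data.frame (subject_id, group, eyo, biomarker_value, sex,
#'   education, mean_fd, family_id) with attribute `"truth"` holding the
#'   generator parameters and mean functions.
#' @export
generate_trajectories <- function(n_mc = 150L, n_nc = 150L,
                                  eyo_range = c(-25, 10), divergence_eyo = -12,
                                  effect_scale = -20, family_sd = 1,
                                  noise_sd = 2, seed = 1L) {
  if (divergence_eyo <= eyo_range[1] || divergence_eyo >= eyo_range[2]) {
    stop("divergence_eyo must lie inside eyo_range")
  }
  ramp <- function(eyo) {
    u <- pmax(0, (eyo - divergence_eyo) / (eyo_range[2] - divergence_eyo))
    raw <- 2 / (1 + exp(-4 * u)) - 1
    raw / (2 / (1 + exp(-4)) - 1)
  }
  mc_mean <- function(eyo) effect_scale * ramp(eyo)
  nc_mean <- function(eyo) rep(0, length(eyo))
  n <- n_mc + n_nc
  with_seed(seed, {
    group <- rep(c("MC", "NC"), c(n_mc, n_nc))
    eyo <- stats::runif(n, eyo_range[1], eyo_range[2])
    sex <- stats::rbinom(n, 1, 0.5)
    education <- round(stats::runif(n, 9, 20))
    mean_fd <- stats::runif(n, 0.04, 0.20)
    family_id <- sprintf("%s_fam_%03d", group,
                         sample.int(max(2L, round(n / 2)), n, replace = TRUE))
    fams <- unique(family_id)
    fam_eff <- stats::rnorm(length(fams), 0, family_sd)
    names(fam_eff) <- fams
    mu <- ifelse(group == "MC", mc_mean(eyo), 0)
    value <- mu + 0.5 * sex + 0.1 * (education - mean(education)) +
      fam_eff[family_id] + stats::rnorm(n, 0, noise_sd)
    out <- data.frame(subject_id = sprintf("traj_%03d", seq_len(n)),
                      group = group, eyo = eyo, biomarker_value = value,
                      sex = sex, education = education, mean_fd = mean_fd,
                      family_id = family_id, stringsAsFactors = FALSE)
    attr(out, "truth") <- list(divergence_eyo = divergence_eyo,
                               effect_scale = effect_scale,
                               family_sd = family_sd, noise_sd = noise_sd,
                               mc_mean = mc_mean, nc_mean = nc_mean,
                               beta_sex = 0.5, beta_education = 0.1)
    out
  })
}

#' Inject additive site mean-shifts (documentation of an unmodeled effect)
#'
#' Adds a per-site constant to every connectivity matrix. The package applies
#' no harmonization; this exists only to let users observe what unharmonized
#' site effects would do to the analysis.
#'
#' @param fc_list named list of connectivity matrices.
#' @param site per-subject site labels.
#' @param shift_sd sd of the per-site z shifts.
#' @param seed integer seed.
#' @return list of shifted matrices.
#' @export
inject_site_effects <- function(fc_list, site, shift_sd = 0.05, seed = 1L) {
  warning("site effects injected; no harmonization is applied downstream")
  sites <- unique(site)
  shifts <- with_seed(seed, stats::rnorm(length(sites), 0, shift_sd))
  names(shifts) <- sites
  out <- lapply(seq_along(fc_list), function(i) {
    z <- fc_list[[i]] + shifts[site[i]]
    diag(z) <- 0
    z
  })
  names(out) <- names(fc_list)
  out
}

#' Multivariate Gaussian ROI time series with a target correlation
#'
#' Draws frames from a zero-mean Gaussian whose correlation equals
#' `tanh(z)` of the target matrix (eigenvalue-clipped to the nearest positive
#' definite matrix when needed).
#'
#' @param fc target Fisher-z connectivity matrix.
#' @param frames number of time points.
#' @param seed integer seed.
#' @return frames x nodes matrix.
#' @export
generate_timeseries <- function(fc, frames = 200L, seed = 1L) {
  r <- tanh(connectivity_matrix(fc))
  diag(r) <- 1
  e <- eigen(r, symmetric = TRUE)
  vals <- pmax(e$values, 1e-6)
  r_pd <- e$vectors %*% (vals * t(e$vectors))
  d <- sqrt(diag(r_pd))
  r_pd <- r_pd / outer(d, d)
  ch <- chol(r_pd)
  with_seed(seed, {
    matrix(stats::rnorm(frames * nrow(r)), frames) %*% ch
  })
}
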