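#' Parcellation of nodes into network modules
#'
#' Builds and validates a parcellation table assigning each region of interest
#' (ROI) to exactly one network module. The atlas used throughout the package
#' defaults mirror a 246-ROI / 13-network cortical-subcortical scheme, but any
#' parcellation with at least 3 nodes and contiguous module ids is accepted.
#'
#' @param module_id integer vector, one entry per ROI, module membership in
#'   `1..M` with all of `1..M` present.
#' @param roi_label optional character vector of ROI names (defaults to
#'   `roi_1, roi_2, ...`).
#' @return An object of class `parcellation`: a data.frame with columns
#'   `roi_id`, `roi_label`, `module_id`.
#' @export
parcellation <- function(module_id, roi_label = NULL) {
  module_id <- as.integer(module_id)
  n <- length(module_id)
  if (n < 3) stop("parcellation needs at least 3 nodes")
  if (anyNA(module_id)) stop("module_id must not contain NA")
  mods <- sort(unique(module_id))
  if (!identical(mods, seq_len(max(mods)))) {
    stop("module ids must be contiguous integers 1..M")
  }
  if (is.null(roi_label)) roi_label <- paste0("roi_", seq_len(n))
  if (length(roi_label) != n) stop("roi_label length must match module_id")
  out <- data.frame(roi_id = seq_len(n), roi_label = as.character(roi_label),
                    module_id = module_id, stringsAsFactors = FALSE)
  class(out) <- c("parcellation", "data.frame")
  out
}

#' Default 246-node, 13-module parcellation
#'
#' Module sizes are drawn as even a split of 246 nodes over 13 networks as
#' possible (sizes 19 or 18), giving the node/network counts of the atlas the
#' package emulates.
#'
#' @param n_nodes total node count.
#' @param n_modules number of network modules.
#' @return A [parcellation].
#' @export
default_parcellation <- function(n_nodes = 246L, n_modules = 13L) {
  sizes <- rep(n_nodes %/% n_modules, n_modules)
  extra <- n_nodes %% n_modules
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  parcellation(rep(seq_len(n_modules), times = sizes))
}

#' Validate a connectivity matrix
#'
#' @param z numeric square matrix of Fisher-z correlations.
#' @return `z` with diagonal zeroed, invisibly checked: symmetric, finite.
#' @export
connectivity_matrix <- function(z) {
  z <- as.matrix(z)
  if (nrow(z) != ncol(z)) stop("connectivity matrix must be square")
  if (any(!is.finite(z))) stop("connectivity matrix must be finite everywhere")
  if (max(abs(z - t(z))) > 1e-8) stop("connectivity matrix must be symmetric")
  z <- (z + t(z)) / 2
  diag(z) <- 0
  z
}

#' Fisher-z functional connectivity from ROI time series
#'
#' Computes zero-lag Pearson correlations between all node pairs and applies
#' the Fisher z-transform. Correlation magnitudes are clipped to
#' `1 - 1e-7` before `atanh` so that perfectly (anti)correlated synthetic
#' series stay finite.
#'
#' @param ts numeric matrix, frames x nodes; at least 3 frames.
#' @return Symmetric Fisher-z matrix with zero diagonal.
#' @export
compute_fc <- function(ts) {
  ts <- as.matrix(ts)
  if (nrow(ts) < 3) stop("need at least 3 frames to estimate connectivity")
  if (any(!is.finite(ts))) stop("time series contain non-finite values")
  v <- apply(ts, 2, stats::var)
  if (any(v == 0)) {
    stop("zero-variance node(s): ", paste(which(v == 0), collapse = ", "))
  }
  r <- stats::cor(ts)
  clip <- 1 - 1e-7
  r <- pmin(pmax(r, -clip), clip)
  z <- atanh(r)
  diag(z) <- 0
  connectivity_matrix(z)
}

# round-half-up; base round() is round-half-even
round_half_up <- function(x) floor(x + 0.5)

#' Density thresholding from a maximum-spanning-tree backbone
#'
#' Retains the strongest edges of a weighted connectivity matrix at a target
#' edge density while guaranteeing a connected graph: a maximum spanning tree
#' on the raw z weights forms the backbone, and remaining edges are added in
#' descending weight order until `round(density * n(n-1)/2)` edges (half-up
#' rounding) are present. Ties in weight are broken by ascending (row, col)
#' index for determinism.
#'
#' @param fc symmetric connectivity matrix (Fisher z).
#' @param density target edge density in (0, 1].
#' @param validate check the input invariants (disable only on matrices
#'   already validated upstream).
#' @return A list of class `thresholded_graph` with elements `weights`
#'   (matrix, zero where the edge is absent), `density`, `edge_count`.
#' @export
mst_threshold <- function(fc, density, validate = TRUE) {
  if (validate) fc <- connectivity_matrix(fc)
  n <- nrow(fc)
  if (density <= 0 || density > 1) stop("density must be in (0, 1]")
  m_all <- n * (n - 1) / 2
  m_target <- round_half_up(density * m_all)
  if (m_target < n - 1) {
    stop(sprintf("density %.4f gives %d edges; need at least n-1 = %d (minimum density %.4f)",
                 density, m_target, n - 1, (n - 1) / m_all))
  }
  ut <- which(upper.tri(fc))
  w <- fc[ut]
  ii <- row(fc)[ut]
  jj <- col(fc)[ut]
  ord <- order(-w, ii, jj)

  # Kruskal maximum spanning tree with union-find (path halving)
  parent <- seq_len(n)
  find_root <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  in_tree <- logical(length(ord))
  accepted <- 0L
  for (k in seq_along(ord)) {
    e <- ord[k]
    ri <- find_root(ii[e]); rj <- find_root(jj[e])
    if (ri != rj) {
      parent[ri] <- rj
      in_tree[k] <- TRUE
      accepted <- accepted + 1L
      if (accepted == n - 1L) break
    }
  }
  sel <- ord[in_tree]
  n_fill <- m_target - (n - 1L)
  if (n_fill > 0) {
    rest <- ord[!ord %in% sel]
    sel <- c(sel, rest[seq_len(n_fill)])
  }
  keep <- ut[sel]
  weights <- matrix(0, n, n)
  weights[keep] <- fc[keep]
  weights <- weights + t(weights)
  if (density <= 0.05 && any(fc[keep] < 0)) {
    warning("negative-weight edges retained at density <= 5%; ",
            "sparse graphs are usually free of negative correlations")
  }
  structure(list(weights = weights, density = density, edge_count = m_target),
            class = "thresholded_graph")
}

# accept either a thresholded_graph or a raw symmetric matrix
as_weight_matrix <- function(g) {
  if (inherits(g, "thresholded_graph")) g$weights else connectivity_matrix(g)
}

# asymmetric signed combination: positive part discounted by the relative
# magnitude of the negative part at that node
asym_combine <- function(pos, neg) {
  tot <- pos + neg
  frac <- ifelse(tot > 0, neg / tot, 0)
  ifelse(tot > 0, pos - frac * neg, 0)
}

#' Signed asymmetrically weighted nodal strength
#'
#' For node i with positive incident weight sum `s+` and absolute negative
#' sum `s-`, strength is `[s+ - (s-/(s+ + s-)) * s-] / (n - 1)`: negative
#' edges are down-weighted by their relative magnitude at the node, so a full
#' (unthresholded) signed matrix still yields meaningful strengths. Isolated
#' nodes get strength 0.
#'
#' @param g `thresholded_graph` or symmetric matrix.
#' @return numeric vector of per-node strength S.
#' @export
signed_strength <- function(g) {
  w <- as_weight_matrix(g)
  n <- nrow(w)
  sp <- rowSums(pmax(w, 0))
  sn <- rowSums(pmax(-w, 0))
  asym_combine(sp, sn) / (n - 1)
}

#' Signed participation coefficient
#'
#' Diversity of a node's connections across modules, computed separately on
#' positive and absolute negative weights (`Pc = 1 - sum_m (k_im/k_i)^2`,
#' zero for edgeless nodes) and combined with the same asymmetric rule as
#' strength: `Pc = Pc+ - (s-/(s+ + s-)) * Pc-`.
#'
#' @param g `thresholded_graph` or symmetric matrix.
#' @param parc [parcellation] covering all nodes.
#' @return numeric vector of per-node participation coefficients in \[-1, 1\].
#' @export
signed_participation <- function(g, parc) {
  w <- as_weight_matrix(g)
  n <- nrow(w)
  if (nrow(parc) != n) stop("parcellation does not cover all nodes")
  mod <- parc$module_id
  if (anyNA(mod)) stop("node with no module assignment")
  mmat <- outer(mod, sort(unique(mod)), "==") * 1
  pc_sign <- function(wpos) {
    k <- rowSums(wpos)
    km <- wpos %*% mmat
    frac <- km / ifelse(k > 0, k, 1)
    ifelse(k > 0, 1 - rowSums(frac^2), 0)
  }
  pcp <- pc_sign(pmax(w, 0))
  pcn <- pc_sign(pmax(-w, 0))
  sp <- rowSums(pmax(w, 0))
  sn <- rowSums(pmax(-w, 0))
  tot <- sp + sn
  frac <- ifelse(tot > 0, sn / tot, 0)
  pcp - frac * pcn
}

#' Within-module strength Z-score
#'
#' Restricts the graph to within-module edges, computes each node's signed
#' asymmetric strength there, and standardizes it against the other nodes of
#' its module (sample standard deviation). Singleton modules and zero-variance
#' modules yield Z = 0.
#'
#' @inheritParams signed_participation
#' @return numeric vector of per-node within-module Z-scores.
#' @export
within_module_z <- function(g, parc) {
  w <- as_weight_matrix(g)
  n <- nrow(w)
  if (nrow(parc) != n) stop("parcellation does not cover all nodes")
  mod <- parc$module_id
  same <- outer(mod, mod, "==")
  win <- w * same
  sp <- rowSums(pmax(win, 0))
  sn <- rowSums(pmax(-win, 0))
  wi <- asym_combine(sp, sn)
  z <- numeric(n)
  for (m in unique(mod)) {
    idx <- which(mod == m)
    if (length(idx) < 2) next
    mu <- mean(wi[idx])
    sdv <- stats::sd(wi[idx])
    if (sdv > 0) z[idx] <- (wi[idx] - mu) / sdv
  }
  z
}

#' Residualize a nodal metric on a per-subject covariate
#'
#' Per node, ordinary least squares of the metric on the covariate across
#' subjects; returns residuals plus the across-subject node mean, so the
#' metric keeps its scale. Used to regress retained scan time (and,
#' optionally, per-ROI gray-matter volume) out of graph metrics.
#'
#' @param values subjects x nodes numeric matrix.
#' @param covariate numeric vector, one value per subject.
#' @return adjusted matrix of the same dimension.
#' @export
residualize_metric <- function(values, covariate) {
  values <- as.matrix(values)
  if (nrow(values) < 3) stop("need at least 3 subjects to residualize")
  if (any(!is.finite(covariate))) stop("covariate must be finite")
  if (length(covariate) != nrow(values)) stop("covariate length must match subject count")
  if (stats::var(covariate) == 0) {
    warning("constant covariate; returning metric unchanged")
    return(values)
  }
  fit <- stats::lm.fit(cbind(1, covariate), values)
  res <- as.matrix(fit$residuals)
  sweep(res, 2, colMeans(values), "+")
}

#' Nodal centrality metrics for one subject
#'
#' Thresholds the subject's connectivity matrix at the requested density
#' (density 1 uses the full matrix) and computes signed strength,
#' participation coefficient, and within-module Z-score.
#'
#' @param fc symmetric Fisher-z connectivity matrix.
#' @param parc [parcellation].
#' @param density edge density in (0, 1].
#' @param subject_id identifier recorded in the output.
#' @return data.frame with columns subject_id, roi, density, S, Pc, Z.
#' @export
compute_nodal_metrics <- function(fc, parc, density = 0.05, subject_id = "subj") {
  g <- mst_threshold(fc, density)
  data.frame(subject_id = subject_id, roi = parc$roi_label, density = density,
             S = signed_strength(g), Pc = signed_participation(g, parc),
             Z = within_module_z(g, parc), stringsAsFactors = FALSE)
}

#' Subjects x nodes metric matrices for a list of connectivity matrices
#'
#' @param fc_list named list of connectivity matrices (names = subject ids).
#' @param parc [parcellation].
#' @param density edge density in (0, 1].
#' @return list with matrices `S`, `Pc`, `Z` (subjects x nodes, rownames =
#'   subject ids) and the `density` used.
#' @export
cohort_metrics <- function(fc_list, parc, density = 0.05) {
  n <- nrow(parc)
  ids <- names(fc_list)
  if (is.null(ids)) ids <- paste0("subj_", seq_along(fc_list))
  S <- Pc <- Z <- matrix(NA_real_, length(fc_list), n,
                         dimnames = list(ids, parc$roi_label))
  for (s in seq_along(fc_list)) {
    g <- mst_threshold(fc_list[[s]], density, validate = FALSE)
    S[s, ] <- signed_strength(g)
    Pc[s, ] <- signed_participation(g, parc)
    Z[s, ] <- within_module_z(g, parc)
  }
  list(S = S, Pc = Pc, Z = Z, density = density)
}

#' Subjects x nodes strength matrix (strength-only fast path)
#'
#' @inheritParams cohort_metrics
#' @return subjects x nodes matrix of signed strength.
#' @export
cohort_strengths <- function(fc_list, parc, density = 0.05) {
  n <- nrow(parc)
  ids <- names(fc_list)
  if (is.null(ids)) ids <- paste0("subj_", seq_along(fc_list))
  S <- matrix(NA_real_, length(fc_list), n, dimnames = list(ids, parc$roi_label))
  for (s in seq_along(fc_list)) {
    S[s, ] <- signed_strength(mst_threshold(fc_list[[s]], density, validate = FALSE))
  }
  S
}
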