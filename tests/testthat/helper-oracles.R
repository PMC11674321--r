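# Independent brute-force oracles used to validate the vectorized
# implementations. These deliberately use naive double loops and textbook
# formulas, not the package's code paths.

random_signed_matrix <- function(n, seed, neg_frac = 0.3) {
  set.seed(seed)
  z <- matrix(0, n, n)
  ut <- upper.tri(z)
  v <- rnorm(sum(ut), 0.2, 0.3)
  flip <- runif(sum(ut)) < neg_frac
  v[flip] <- -abs(v[flip])
  z[ut] <- v
  z <- z + t(z)
  diag(z) <- 0
  z
}

bf_strength <- function(w) {
  n <- nrow(w)
  out <- numeric(n)
  for (i in seq_len(n)) {
    sp <- 0; sn <- 0
    for (j in seq_len(n)) {
      if (j == i) next
      if (w[i, j] > 0) sp <- sp + w[i, j] else sn <- sn + abs(w[i, j])
    }
    out[i] <- if (sp + sn > 0) (sp - (sn / (sp + sn)) * sn) / (n - 1) else 0
  }
  out
}

bf_participation <- function(w, mod) {
  n <- nrow(w)
  mods <- sort(unique(mod))
  out <- numeric(n)
  for (i in seq_len(n)) {
    pc <- c(pos = 0, neg = 0)
    deg <- c(pos = 0, neg = 0)
    for (sgn in c("pos", "neg")) {
      wi <- if (sgn == "pos") pmax(w[i, ], 0) else pmax(-w[i, ], 0)
      k <- sum(wi)
      deg[sgn] <- k
      if (k > 0) {
        acc <- 0
        for (m in mods) acc <- acc + (sum(wi[mod == m]) / k)^2
        pc[sgn] <- 1 - acc
      }
    }
    tot <- deg["pos"] + deg["neg"]
    frac <- if (tot > 0) deg["neg"] / tot else 0
    out[i] <- pc["pos"] - frac * pc["neg"]
  }
  unname(out)
}

bf_within_z <- function(w, mod) {
  n <- nrow(w)
  wi <- numeric(n)
  for (i in seq_len(n)) {
    sp <- 0; sn <- 0
    for (j in seq_len(n)) {
      if (j == i || mod[j] != mod[i]) next
      if (w[i, j] > 0) sp <- sp + w[i, j] else sn <- sn + abs(w[i, j])
    }
    wi[i] <- if (sp + sn > 0) sp - (sn / (sp + sn)) * sn else 0
  }
  out <- numeric(n)
  for (m in unique(mod)) {
    idx <- which(mod == m)
    if (length(idx) < 2) next
    s <- sd(wi[idx])
    if (s > 0) out[idx] <- (wi[idx] - mean(wi[idx])) / s
  }
  out
}

# BH step-up by direct threshold scanning
bf_bh_flags <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  passed <- which(p[ord] <= seq_len(m) * q / m)
  flags <- logical(m)
  if (length(passed) > 0) flags[ord[seq_len(max(passed))]] <- TRUE
  flags
}

bf_bh_adjust <- function(p) {
  m <- length(p)
  ord <- order(p, decreasing = TRUE)
  adj <- numeric(m)
  running <- 1
  for (r in seq_along(ord)) {
    i <- ord[r]
    rank_i <- m - r + 1
    running <- min(running, p[i] * m / rank_i)
    adj[i] <- running
  }
  adj
}

# simple-regression oracle via explicit normal equations (2x2 solve)
bf_ols <- function(y, x) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  res <- y - X %*% beta
  tss <- sum((y - mean(y))^2)
  list(intercept = beta[1], slope = beta[2],
       r_squared = if (tss > 0) 1 - sum(res^2) / tss else 0)
}

# maximum-spanning-tree edge set via igraph (independent of the package's
# Kruskal), for matrices with distinct weights
igraph_mst_edges <- function(z) {
  g <- igraph::graph_from_adjacency_matrix(-z, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  t <- igraph::mst(g, weights = igraph::E(g)$weight)
  el <- igraph::as_edgelist(t, names = FALSE)
  sort(apply(el, 1, function(e) paste(sort(e), collapse = "-")))
}

edge_set <- function(weights) {
  idx <- which(upper.tri(weights) & weights != 0, arr.ind = TRUE)
  sort(paste(idx[, 1], idx[, 2], sep = "-"))
}

is_connected_graph <- function(weights) {
  g <- igraph::graph_from_adjacency_matrix(weights != 0, mode = "undirected",
                                           diag = FALSE)
  igraph::is_connected(g)
}

# small helper: reference profile straight from a vector of node means
ref_from_means <- function(mu, percentile = 85) {
  build_reference(rbind(mu, mu), percentile)
}
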