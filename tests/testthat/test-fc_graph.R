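test_that("compute_fc matches closed-form Pearson + Fisher transform", {
  x <- c(1, 2, 3, 4)
  y <- c(1, 2, 3, 5)
  fc <- compute_fc(cbind(x, y))
  # closed form: r = S_xy / sqrt(S_xx S_yy) = 6.5 / sqrt(5 * 8.75)
  r_hand <- 6.5 / sqrt(5 * 8.75)
  expect_equal(fc[1, 2], atanh(r_hand), tolerance = 1e-12)
  expect_equal(fc[1, 2], 2.3709767, tolerance = 1e-6)
  expect_equal(fc[2, 1], fc[1, 2])
  expect_equal(unname(diag(fc)), c(0, 0))
})

test_that("compute_fc clips perfect correlations symmetrically", {
  x <- rnorm(20)
  fc <- compute_fc(cbind(x, x + 0, -x))
  zmax <- atanh(1 - 1e-7)
  expect_equal(fc[1, 2], zmax)
  expect_equal(fc[1, 3], -zmax)
  expect_true(all(is.finite(fc)))
})

test_that("compute_fc rejects degenerate input", {
  expect_error(compute_fc(cbind(c(1, 1, 1, 1), rnorm(4))), "zero-variance")
  expect_error(compute_fc(matrix(rnorm(4), 2, 2)), "frames")
})

test_that("mst_threshold backbone-only density returns a maximum spanning tree", {
  skip_if_not_installed("igraph")
  for (seed in 1:5) {
    z <- random_signed_matrix(12, seed)
    d_min <- (12 - 1) / (12 * 11 / 2)
    g <- mst_threshold(z, d_min)
    expect_equal(g$edge_count, 11)
    expect_true(is_connected_graph(g$weights))
    expect_identical(edge_set(g$weights), igraph_mst_edges(z))
  }
})

test_that("mst_threshold equals Kruskal + greedy-fill oracle on 5-node instances", {
  for (seed in 1:20) {
    set.seed(seed)
    z <- matrix(0, 5, 5)
    z[upper.tri(z)] <- sample(seq(-0.5, 0.9, length.out = 10))  # distinct weights
    z <- z + t(z)
    g <- mst_threshold(z, 0.6)  # 6 of 10 edges
    expect_equal(g$edge_count, 6)
    # oracle: MST edges plus strongest non-tree edges
    mst_e <- igraph_mst_edges(z)
    ut <- which(upper.tri(z))
    ids <- paste(row(z)[ut], col(z)[ut], sep = "-")
    ord <- ids[order(-z[ut])]
    fill <- setdiff(ord, mst_e)
    oracle <- sort(c(mst_e, fill[seq_len(6 - length(mst_e))]))
    expect_identical(edge_set(g$weights), oracle)
  }
})

test_that("mst_threshold at density 1 is the identity and low densities stay connected", {
  z <- random_signed_matrix(30, 99)
  g1 <- mst_threshold(z, 1)
  expect_equal(g1$weights, z)
  expect_equal(g1$edge_count, 30 * 29 / 2)
  for (d in c(0.1, 0.3, 0.7)) {
    g <- suppressWarnings(mst_threshold(z, d))
    expect_equal(g$edge_count, floor(d * 435 + 0.5))
    expect_true(is_connected_graph(g$weights))
    nz <- g$weights[g$weights != 0]
    expect_true(all(nz %in% z))  # retained edges keep their weights
  }
  expect_error(mst_threshold(z, 0.01), "minimum density")
})

test_that("signed centrality metrics agree with brute-force oracles", {
  parc <- parcellation(rep(1:4, each = 5))
  for (seed in 1:10) {
    z <- random_signed_matrix(20, seed)
    g <- suppressWarnings(mst_threshold(z, 0.5))
    for (w in list(z, g$weights)) {
      expect_equal(signed_strength(w), bf_strength(w), tolerance = 1e-12)
      expect_equal(signed_participation(w, parc), bf_participation(w, parc$module_id),
                   tolerance = 1e-12)
      expect_equal(within_module_z(w, parc), bf_within_z(w, parc$module_id),
                   tolerance = 1e-12)
    }
  }
})

test_that("signed strength hand examples hold", {
  # 4 nodes: node 1 has s+ = 3 (to nodes 2,3) and s- = 1 (to node 4)
  w <- matrix(0, 4, 4)
  w[1, 2] <- 2; w[1, 3] <- 1; w[1, 4] <- -1
  w <- w + t(w)
  expect_equal(signed_strength(w)[1], (3 - 0.25) / 3, tolerance = 1e-12)
  # all-positive graph: plain strength / (n-1)
  wp <- abs(random_signed_matrix(10, 1))
  expect_equal(signed_strength(wp), rowSums(wp) / 9, tolerance = 1e-12)
  # isolated node
  w0 <- matrix(0, 3, 3); w0[1, 2] <- w0[2, 1] <- 1
  expect_equal(signed_strength(w0)[3], 0)
})

test_that("participation coefficient hand examples hold", {
  parc <- parcellation(c(1, 1, 2, 2))
  # node 1: all edges within module 1 -> Pc = 0
  w <- matrix(0, 4, 4); w[1, 2] <- 1; w <- w + t(w)
  expect_equal(signed_participation(w, parc)[1], 0)
  # node 1: weight 2 in each of two modules -> 1 - 2*(0.5)^2 = 0.5
  w <- matrix(0, 4, 4); w[1, 2] <- 2; w[1, 3] <- 2; w <- w + t(w)
  expect_equal(signed_participation(w, parc)[1], 0.5)
  # edgeless node -> 0
  expect_equal(signed_participation(w, parc)[4], 0)
})

test_that("within-module Z hand examples hold", {
  parc <- parcellation(c(1, 1, 1, 2, 2, 3))
  # module 1 within-strengths {1, 2, 3}: top node has Z = 1 with sample sd = 1
  w <- matrix(0, 6, 6)
  w[1, 3] <- 1; w[2, 3] <- 2  # node1 = 1, node2 = 2, node3 = 3
  w <- w + t(w)
  z <- within_module_z(w, parc)
  expect_equal(z[1:3], c(-1, 0, 1), tolerance = 1e-12)
  expect_equal(z[3], 1)
  # identical nodes in a module -> all Z = 0; singleton module -> 0
  w2 <- matrix(0.3, 6, 6); diag(w2) <- 0
  z2 <- within_module_z(w2, parc)
  expect_equal(z2, rep(0, 6))
})

test_that("graph metrics are equivariant to node relabeling", {
  parc <- parcellation(rep(1:3, each = 7))
  z <- random_signed_matrix(21, 42)
  perm <- sample(21)
  zp <- z[perm, perm]
  parc_p <- parcellation(parc$module_id[perm])
  expect_equal(signed_strength(zp), signed_strength(z)[perm], tolerance = 1e-12)
  expect_equal(signed_participation(zp, parc_p),
               signed_participation(z, parc)[perm], tolerance = 1e-12)
  expect_equal(within_module_z(zp, parc_p),
               within_module_z(z, parc)[perm], tolerance = 1e-12)
})

test_that("residualize_metric removes a linear covariate and keeps node means", {
  set.seed(1)
  cov <- rnorm(12)
  # exact linear relation: metric = 2*cov + 5 per node -> constant output
  m <- outer(2 * cov + 5, rep(1, 4))
  adj <- residualize_metric(m, cov)
  expect_equal(adj, matrix(colMeans(m), 12, 4, byrow = TRUE), tolerance = 1e-10)
  # orthogonal covariate leaves the metric unchanged
  metric <- matrix(rnorm(12 * 4), 12, 4)
  cov_orth <- rnorm(12)
  cov_orth <- residuals(lm(cov_orth ~ metric))  # orthogonal to every column
  expect_equal(residualize_metric(metric, cov_orth), metric, tolerance = 1e-8)
  # hand OLS: single node, covariate (0,1), metric (1,3) -> residual+mean = (2,2)
  expect_equal(unname(residualize_metric(matrix(c(1, 3, 2, 2, 2), 5, 1),
                                         c(0, 1, 0.5, 0.5, 0.5))[1:2, 1]),
               c(2, 2), tolerance = 1e-10)
  expect_warning(residualize_metric(metric, rep(1, 12)), "constant")
})

test_that("parcellation and connectivity constructors enforce invariants", {
  expect_error(parcellation(c(1, 3, 3)), "contiguous")
  expect_error(parcellation(c(1, 2)), "at least 3")
  expect_equal(nrow(default_parcellation()), 246)
  expect_equal(length(unique(default_parcellation()$module_id)), 13)
  m <- matrix(rnorm(9), 3, 3)
  expect_error(connectivity_matrix(m), "symmetric")
  m[1, 1] <- Inf
  expect_error(connectivity_matrix(m), "finite")
})
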