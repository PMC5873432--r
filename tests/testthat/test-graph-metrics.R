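test_that("the default sparsity grid spans 0.5-0.9 in 21 steps", {
  g <- sparsity_grid()
  expect_length(g, 21)
  expect_equal(g[1], 0.5)
  expect_equal(g[21], 0.9)
  expect_equal(unique(round(diff(g), 10)), 0.02)
  expect_error(sparsity_grid(0.9, 0.5), "lo <= hi")
})

test_that("thresholding keeps exactly the strongest |Cij|", {
  C <- fixed_corr(5, seed = 13)
  v <- abs(C[upper.tri(C)])
  g <- threshold_at_sparsity(C, 0.8)        # 10 pairs -> keep top 2
  expect_equal(g$n_edges, 2)
  kept <- abs(C[g$adjacency & upper.tri(C)])
  expect_setequal(kept, sort(v, decreasing = TRUE)[1:2])
  expect_true(all(kept > g$threshold))

  # strong negative correlations are retained (absolute-value rule)
  C2 <- C / 2
  C2[1, 2] <- C2[2, 1] <- -0.95
  g2 <- threshold_at_sparsity(C2, 0.9)      # keep top 1
  expect_true(g2$adjacency[1, 2])

  tied <- matrix(0.5, 4, 4); diag(tied) <- 0
  expect_error(threshold_at_sparsity(tied, 0.5), "tie-degenerate")
  expect_error(threshold_at_sparsity(matrix(0, 1, 1), 0.5), "2 regions")
})

test_that("analytic boundary cases of the four metrics hold", {
  k5 <- bg_complete(5)
  expect_equal(clustering_index(k5)$global, 1)
  expect_equal(path_length(bg_complete(4))$L, 1)
  expect_equal(global_efficiency(bg_complete(6)), 1)
  expect_equal(as.numeric(local_efficiency(bg_complete(4))), 1)

  # path a-b-c
  P <- matrix(0, 3, 3); P[1, 2] <- P[2, 1] <- P[2, 3] <- P[3, 2] <- 1
  p <- bg(P)
  expect_equal(clustering_index(p)$global, 0)
  expect_equal(path_length(p)$L, 4 / 3)
  bc <- betweenness_centrality(p)
  expect_equal(bc$betweenness, c(0, 1, 0))
  expect_equal(attr(bc, "mean_betweenness"), 1 / 3)
  expect_equal(bc$nbc, c(0, 3, 0))
  expect_identical(identify_hubs(bc)$region_id, "n02")

  # two disjoint edges on 4 nodes: 4 of 12 ordered pairs at d = 1
  DD <- matrix(0, 4, 4); DD[1, 2] <- DD[2, 1] <- DD[3, 4] <- DD[4, 3] <- 1
  expect_equal(global_efficiency(bg(DD)), 1 / 3)
  pl <- path_length(bg(DD))
  expect_equal(pl$disconnected_fraction, 2 / 3)

  # star: leaves have degree 1, the center's neighbourhood is edgeless
  S <- matrix(0, 6, 6); S[1, 2:6] <- S[2:6, 1] <- 1
  expect_equal(as.numeric(local_efficiency(bg(S))), 0)

  # empty graph
  E <- bg(matrix(0, 4, 4))
  expect_equal(global_efficiency(E), 0)
  expect_false(path_length(E)$defined)

  # complete graph: all betweenness 0, zero flag set
  bck <- betweenness_centrality(bg_complete(5))
  expect_true(attr(bck, "zero_flag"))
  expect_equal(bck$nbc, rep(0, 5))
})

test_that("metrics equal brute-force oracles on random graphs", {
  set.seed(14)
  for (i in 1:40) {
    n <- sample(4:10, 1)
    A <- rand_adjacency(n, runif(1, 0.15, 0.8))
    g <- bg(A)
    expect_equal(clustering_index(g)$global, oracle_clustering(A)$global,
                 tolerance = 1e-12)
    expect_equal(path_length(g)$L, oracle_path_length(A), tolerance = 1e-12)
    expect_equal(global_efficiency(g), oracle_global_efficiency(A),
                 tolerance = 1e-12)
    expect_equal(as.numeric(local_efficiency(g)), oracle_local_efficiency(A),
                 tolerance = 1e-12)
    expect_equal(betweenness_centrality(g)$betweenness, oracle_betweenness(A),
                 tolerance = 1e-9)
  }
})

test_that("hub selection uses a strict cutoff and NBC ordering", {
  nm <- data.frame(region_id = c("a", "b", "c"), nbc = c(3, 1.5, 0.2))
  expect_identical(identify_hubs(nm)$region_id, "a")
  nm2 <- data.frame(region_id = letters[1:4], nbc = rep(1, 4))
  expect_equal(nrow(identify_hubs(nm2)), 0)
})

test_that("normalized betweenness averages to 1 and metrics stay in range", {
  set.seed(15)
  for (i in 1:25) {
    A <- rand_adjacency(sample(5:12, 1), runif(1, 0.2, 0.7))
    g <- bg(A)
    bc <- betweenness_centrality(g)
    if (!attr(bc, "zero_flag"))
      expect_equal(mean(bc$nbc), 1, tolerance = 1e-12)
    gm <- graph_metrics(g)
    expect_gte(gm$C, 0); expect_lte(gm$C, 1)
    expect_gte(gm$Eglob, 0); expect_lte(gm$Eglob, 1)
    expect_gte(gm$Eloc, 0); expect_lte(gm$Eloc, 1)
  }
})

test_that("edge sets are nested and efficiency is monotone over the grid", {
  set.seed(16)
  grid <- sparsity_grid(0.5, 0.9, 0.05)
  for (i in 1:10) {
    C <- rand_corr(20)
    graphs <- lapply(grid, function(s) threshold_at_sparsity(C, s))
    for (k in 2:length(graphs)) {
      a_lo <- graphs[[k - 1]]$adjacency
      a_hi <- graphs[[k]]$adjacency
      expect_true(all(a_lo[a_hi]))   # denser graph contains the sparser one
    }
    eg <- vapply(graphs, global_efficiency, numeric(1))
    expect_true(all(diff(eg) <= 1e-12))
    deg <- vapply(graphs, function(g) sum(g$adjacency), numeric(1))
    expect_true(all(diff(deg) <= 0))
  }
})

test_that("property curves carry trapezoid AUCs and flag degenerate grids", {
  expect_equal(auc_trapezoid(seq(0.5, 0.9, 0.02), rep(1, 21)), 0.4)
  expect_warning(a <- auc_trapezoid(0.5, 1), "single-point")
  expect_equal(a, 0)

  C <- quick_corr(40, small_regions(6), h = 0.5, seed = 17)
  pc <- property_curves(C, sparsity_grid(0.5, 0.9, 0.1))
  for (curve in pc) expect_curve_invariants(curve)
  expect_true(all(diff(pc$Eglob$values) <= 1e-12))
})

test_that("graph_metrics agrees with the individual metric functions", {
  C <- quick_corr(30, small_regions(5), seed = 18)
  g <- threshold_at_sparsity(C, 0.7)
  gm <- graph_metrics(g)
  expect_equal(gm$C, clustering_index(g)$global)
  expect_equal(gm$L, path_length(g)$L)
  expect_equal(gm$Eglob, global_efficiency(g))
  expect_equal(gm$Eloc, as.numeric(local_efficiency(g)))
})
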