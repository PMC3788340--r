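test_that("binarization keeps round-half-up K of the strongest pairs", {
  set.seed(7)
  z4 <- matrix(0, 4, 4)
  z4[upper.tri(z4)] <- runif(6)
  z4 <- z4 + t(z4)
  g <- binarize_by_sparsity(z4, 0.5)
  expect_equal(g$n_edges, 3L)          # 0.5 * 6 = 3

  # 10 pairs at s = 0.25: 2.5 rounds *up* to 3
  z5 <- matrix(0, 5, 5)
  z5[upper.tri(z5)] <- runif(10)
  z5 <- z5 + t(z5)
  expect_equal(binarize_by_sparsity(z5, 0.25)$n_edges, 3L)

  # 110 ROIs at s = 0.10: K = round_half_up(599.5) = 600
  z110 <- matrix(0, 110, 110)
  z110[upper.tri(z110)] <- rnorm(5995)
  z110 <- z110 + t(z110)
  expect_equal(binarize_by_sparsity(z110, 0.10)$n_edges, 600L)
})

test_that("binarization selects exactly the top-ranked signed pairs", {
  z <- matrix(-1, 4, 4)
  diag(z) <- 0
  z[1, 2] <- z[2, 1] <- 3
  z[1, 3] <- z[3, 1] <- 2.5
  z[2, 4] <- z[4, 2] <- 2
  z[3, 4] <- z[4, 3] <- -5   # strongly negative, must not be picked
  g <- binarize_by_sparsity(z, 0.5)
  expect_equal(g$adjacency[1, 2], 1L)
  expect_equal(g$adjacency[1, 3], 1L)
  expect_equal(g$adjacency[2, 4], 1L)
  expect_equal(g$n_edges, 3L)
  expect_equal(g$adjacency[3, 4], 0L)
  # absolute ranking flips that choice
  ga <- binarize_by_sparsity(z, 0.5, rank_by = "absolute")
  expect_equal(ga$adjacency[3, 4], 1L)
})

test_that("an all-ties matrix falls back to lexicographic selection", {
  z <- matrix(1, 4, 4)
  diag(z) <- 0
  expect_warning(g <- binarize_by_sparsity(z, 0.5), "tie")
  expect_equal(g$edges, rbind(c(1, 2), c(1, 3), c(1, 4)))
})

test_that("degenerate sparsities are rejected", {
  z <- matrix(0.5, 10, 10)
  diag(z) <- 0
  expect_error(binarize_by_sparsity(z, 0.002), "no edges")
  expect_error(binarize_by_sparsity(z, 1.2), "must be")
})

test_that("the path census reports known distances and path counts", {
  k4 <- binary_graph(complete_adj(4))
  cen <- path_census(k4)
  expect_true(all(cen$distances[row(cen$distances) != col(cen$distances)] == 1))

  p3 <- binary_graph(path_adj(3))
  cen3 <- path_census(p3)
  expect_equal(cen3$distances[1, 3], 2)
  expect_equal(cen3$path_counts[1, 3], 1)

  f5 <- fixture5()
  cen5 <- path_census(f5)
  expect_equal(cen5$distances[1, 5], 3)
  expect_equal(cen5$distances[2, 5], 3)
  expect_equal(cen5$distances[1, 4], 2)
  # two shortest 1->4 paths (via 2? no: via 3 only) vs 2->... check counts
  expect_equal(cen5$path_counts[1, 4], 1)

  # disconnected pair: infinite distance, zero paths
  g <- binary_graph(edges = rbind(c(1, 2)), n_nodes = 3)
  cen_d <- path_census(g)
  expect_equal(cen_d$distances[1, 3], Inf)
  expect_equal(cen_d$path_counts[1, 3], 0)
})

test_that("global metrics match closed forms on canonical graphs", {
  k6 <- global_metrics(binary_graph(complete_adj(6)))
  expect_equal(k6$c_p, 1)
  expect_equal(k6$l_p, 1)
  expect_equal(k6$e_glob, 1)
  expect_equal(k6$e_loc, 1)

  s5 <- global_metrics(binary_graph(star_adj(5)))
  expect_equal(s5$c_p, 0)
  expect_equal(s5$e_loc, 0)

  f5 <- global_metrics(fixture5())
  expect_equal(f5$c_p, 7 / 15)
  expect_equal(f5$e_glob, 43 / 60)
  expect_equal(f5$l_p, 60 / 43)

  ring <- global_metrics(binary_graph(ring_lattice_adj(50, 4)))
  expect_equal(ring$c_p, 0.5, tolerance = 1e-12)
})

test_that("the arithmetic path-length convention is available as an option", {
  f5 <- global_metrics(fixture5(), path_length = "arithmetic")
  # unordered distances: five 1s, three 2s, two 3s -> mean 17/10
  expect_equal(f5$l_p, 1.7)
  harmonic <- global_metrics(fixture5())
  expect_equal(harmonic$l_p * harmonic$e_glob, 1, tolerance = 1e-12)
})

test_that("nodal metrics match closed forms on canonical graphs", {
  n <- 7
  star <- nodal_metrics(binary_graph(star_adj(n)))
  expect_equal(star$degree[1], n - 1)
  expect_equal(star$betweenness[1], (n - 1) * (n - 2) / 2)
  expect_equal(star$betweenness[-1], rep(0, n - 1))

  p3 <- nodal_metrics(binary_graph(path_adj(3)))
  expect_equal(p3$betweenness[2], 1)

  f5 <- nodal_metrics(fixture5())
  expect_equal(f5$betweenness[3], 4)
  expect_equal(f5$betweenness[4], 3)
  expect_equal(f5$efficiency[5], 13 / 24)
})

test_that("metrics agree with exhaustive enumeration on random graphs", {
  for (i in 1:60) {
    n <- sample(4:12, 1)
    adj <- random_adj(n, runif(1, 0.1, 0.9), seed = 100 + i)
    g <- binary_graph(adj)
    cen <- path_census(g)
    oc <- oracle_census(adj)
    expect_identical(cen$distances, oc$distances)
    expect_identical(cen$path_counts, oc$path_counts)
    gm <- global_metrics(g)
    expect_equal(gm$c_p, oracle_clustering(adj))
    expect_equal(gm$e_glob, oracle_global_efficiency(adj))
    expect_equal(gm$e_loc, oracle_local_efficiency(adj))
    nm <- nodal_metrics(g)
    expect_equal(nm$degree, rowSums(adj))
    expect_equal(nm$efficiency, oracle_nodal_efficiency(adj))
    expect_equal(nm$betweenness, oracle_betweenness(adj), tolerance = 1e-10)
  }
})

test_that("metrics agree with an independent graph library", {
  for (i in 1:10) {
    n <- sample(10:30, 1)
    adj <- random_adj(n, runif(1, 0.15, 0.5), seed = 300 + i)
    g <- binary_graph(adj)
    ig <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    expect_equal(path_census(g)$distances, unname(igraph::distances(ig)))
    expect_equal(nodal_metrics(g)$betweenness,
                 unname(igraph::betweenness(ig)), tolerance = 1e-10)
    expect_equal(global_metrics(g)$c_p,
                 mean(igraph::transitivity(ig, type = "localundirected",
                                           isolates = "zero")))
  }
})

test_that("degree sums, efficiency bounds and the path-length identity hold", {
  for (i in 1:20) {
    n <- sample(5:12, 1)
    adj <- random_adj(n, runif(1, 0.2, 0.8), seed = 200 + i)
    g <- binary_graph(adj)
    nm <- nodal_metrics(g)
    gm <- global_metrics(g)
    expect_equal(sum(nm$degree), 2 * g$n_edges)
    expect_true(all(nm$efficiency >= 0 & nm$efficiency <= 1))
    expect_true(all(nm$betweenness >= -1e-12))
    expect_true(gm$c_p >= 0 && gm$c_p <= 1)
    if (gm$e_glob > 0) {
      expect_equal(gm$l_p * gm$e_glob, 1, tolerance = 1e-12)
    }
  }
})

test_that("adding an edge never decreases global or nodal efficiency", {
  set.seed(8)
  for (i in 1:10) {
    adj <- random_adj(8, 0.3, seed = 400 + i)
    absent <- which(upper.tri(adj) & adj == 0, arr.ind = TRUE)
    if (nrow(absent) == 0) next
    pick <- absent[sample.int(nrow(absent), 1), ]
    adj2 <- adj
    adj2[pick[1], pick[2]] <- adj2[pick[2], pick[1]] <- 1L
    before <- global_metrics(binary_graph(adj))
    after <- global_metrics(binary_graph(adj2))
    expect_gte(after$e_glob, before$e_glob - 1e-12)
    nb <- nodal_metrics(binary_graph(adj))$efficiency
    na_ <- nodal_metrics(binary_graph(adj2))$efficiency
    expect_true(all(na_ >= nb - 1e-12))
  }
})

test_that("metrics are equivariant under node relabeling", {
  adj <- random_adj(9, 0.4, seed = 500)
  set.seed(9)
  perm <- sample(9)
  padj <- adj[perm, perm]
  nm <- nodal_metrics(binary_graph(adj))
  pnm <- nodal_metrics(binary_graph(padj))
  expect_equal(pnm$degree, nm$degree[perm])
  expect_equal(pnm$efficiency, nm$efficiency[perm])
  expect_equal(pnm$betweenness, nm$betweenness[perm], tolerance = 1e-10)
  expect_equal(global_metrics(binary_graph(adj)),
               global_metrics(binary_graph(padj)))
})
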