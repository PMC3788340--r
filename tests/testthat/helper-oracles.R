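# Exhaustive brute-force oracles for small graphs, written independently of
# the package's BFS/Brandes kernels: distances and shortest-path counts come
# from adjacency-matrix powers ((A^d)_ij counts walks of length d, and every
# length-d walk between nodes at distance d is a shortest path), betweenness
# from the pair-dependency identity, and the metric formulas are transcribed
# directly.

oracle_census <- function(adj) {
  n <- nrow(adj)
  dist <- matrix(Inf, n, n)
  counts <- matrix(0, n, n)
  diag(dist) <- 0
  diag(counts) <- 1
  p <- diag(n)
  for (d in seq_len(n - 1)) {
    p <- p %*% adj
    newly <- is.infinite(dist) & p > 0
    dist[newly] <- d
    counts[newly] <- p[newly]
  }
  list(distances = dist, path_counts = counts)
}

oracle_betweenness <- function(adj) {
  cen <- oracle_census(adj)
  d <- cen$distances
  s <- cen$path_counts
  n <- nrow(adj)
  btw <- numeric(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n - 1)) {
      for (k in seq.int(j + 1, n)) {
        if (j == i || k == i || s[j, k] == 0) next
        if (is.finite(d[j, i]) && is.finite(d[i, k]) &&
            d[j, k] == d[j, i] + d[i, k]) {
          btw[i] <- btw[i] + s[j, i] * s[i, k] / s[j, k]
        }
      }
    }
  }
  btw
}

oracle_global_efficiency <- function(adj) {
  n <- nrow(adj)
  if (n < 2) return(0)
  d <- oracle_census(adj)$distances
  inv <- 1 / d
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

oracle_clustering <- function(adj) {
  n <- nrow(adj)
  terms <- vapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] == 1)
    if (length(nb) < 2) return(0)
    e_i <- sum(adj[nb, nb]) / 2
    e_i / (length(nb) * (length(nb) - 1) / 2)
  }, numeric(1))
  mean(terms)
}

oracle_local_efficiency <- function(adj) {
  n <- nrow(adj)
  mean(vapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] == 1)
    if (length(nb) < 2) return(0)
    oracle_global_efficiency(adj[nb, nb, drop = FALSE])
  }, numeric(1)))
}

oracle_nodal_efficiency <- function(adj) {
  n <- nrow(adj)
  d <- oracle_census(adj)$distances
  inv <- 1 / d
  diag(inv) <- 0
  rowSums(inv) / (n - 1)
}

# deterministic Bernoulli adjacency at a given density
random_adj <- function(n, p, seed) {
  set.seed(seed)
  adj <- matrix(0L, n, n)
  adj[upper.tri(adj)] <- as.integer(stats::runif(n * (n - 1) / 2) < p)
  adj + t(adj)
}

complete_adj <- function(n) matrix(1L, n, n) - diag(1L, n)

star_adj <- function(n) {
  adj <- matrix(0L, n, n)
  adj[1, 2:n] <- adj[2:n, 1] <- 1L
  adj
}

path_adj <- function(n) {
  adj <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) adj[i, i + 1] <- adj[i + 1, i] <- 1L
  adj
}

ring_lattice_adj <- function(n, k) {
  adj <- matrix(0L, n, n)
  for (d in seq_len(k / 2)) {
    j <- (seq_len(n) - 1 + d) %% n + 1
    adj[cbind(seq_len(n), j)] <- 1L
    adj[cbind(j, seq_len(n))] <- 1L
  }
  adj
}

# the 5-node worked example used across the metric tests
fixture5 <- function() {
  binary_graph(edges = rbind(c(1, 2), c(1, 3), c(2, 3), c(3, 4), c(4, 5)),
               n_nodes = 5)
}

# minimal subject_ts construction for tests that bypass the generator
make_ts <- function(data, tr = 2.34, group = "A", id = "sub-test",
                    nuisance = NULL) {
  structure(list(subject_id = id, group = group, data = as.matrix(data),
                 tr_seconds = tr, training_years = NA_real_,
                 nuisance = nuisance),
            class = "subject_ts")
}
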