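# C_P and harmonic L_P from an edge list, the two quantities needed from
# each null network. Kept lean: no neighbor-subgraph or betweenness work.
cp_lp_of_edges <- function(edges, n) {
  c_p <- mean(.local_clustering_cpp(edges, n))
  d <- .graph_census_cpp(edges, n, want_counts = FALSE,
                         want_betweenness = FALSE)$distances
  inv <- 1 / d
  diag(inv) <- 0
  e_glob <- sum(inv) / (n * (n - 1))
  list(c_p = c_p, l_p = if (e_glob > 0) 1 / e_glob else Inf)
}

#' Degree-preserving (Maslov-Sneppen) rewiring
#'
#' Randomizes a binary graph by repeated double-edge swaps: two edges
#' `(a,b)` and `(c,d)` with four distinct endpoints are replaced by `(a,d)`
#' and `(c,b)` unless either replacement already exists, which preserves
#' every node's degree and the edge count exactly.
#' `ceiling(swap_factor * |E|)` swaps are attempted. A graph admitting no
#' legal swap within the attempt budget (e.g. a triangle) is returned
#' unchanged with a message.
#'
#' @param g A `binary_graph` with at least 2 edges.
#' @param swap_factor Attempted swaps per edge (default 10, standard
#'   rewiring depth; 0 returns the graph unchanged).
#' @param seed Integer seed; the rewiring is reproducible from it.
#' @return A `binary_graph` with the same degree sequence.
#' @export
rewire_degree_preserving <- function(g, swap_factor = 10, seed) {
  stopifnot(inherits(g, "binary_graph"))
  if (g$n_edges < 2) stop("need at least 2 edges to rewire", call. = FALSE)
  assert_number(swap_factor, "swap_factor", lower = 0)
  niter <- ceiling(swap_factor * g$n_edges)
  if (niter == 0) return(g)
  rw <- with_seed(as.integer(seed), {
    .rewire_ms_cpp(graph_edges(g), g$n_nodes, as.integer(niter))
  })
  if (rw$swaps == 0) {
    message(sprintf("no legal swap found in %d attempts: graph returned unchanged",
                    niter))
    return(g)
  }
  adj <- matrix(0L, g$n_nodes, g$n_nodes)
  adj[rw$edges] <- 1L
  adj <- adj + t(adj)
  dimnames(adj) <- dimnames(g$adjacency)
  res <- g
  res$adjacency <- adj
  res$edges <- rw$edges
  res
}

#' Small-world normalization against degree-matched random networks
#'
#' Generates `n_null` independent degree-preserving rewirings of `g`,
#' averages their clustering coefficients and (harmonic) characteristic
#' path lengths, and returns the normalized small-world parameters
#' `gamma = C_P / mean(C_P^rand)`, `lambda = L_P / mean(L_P^rand)` and
#' `sigma = gamma / lambda`. Nulls with `C_P = 0` or infinite `L_P` are
#' excluded from the means (with a message reporting the count); if every
#' null is degenerate an error is raised.
#'
#' @param g A `binary_graph`.
#' @param n_null Number of null networks (default 100).
#' @param swap_factor Attempted swaps per edge for each null (default 10).
#' @param seed Integer seed for the null ensemble.
#' @return List with `gamma`, `lam`, `sigma`, `c_rand`, `l_rand`, `n_null`,
#'   `n_used`, and the real graph's `c_p`, `l_p`.
#' @export
normalize_small_world <- function(g, n_null = 100, swap_factor = 10, seed) {
  stopifnot(inherits(g, "binary_graph"))
  assert_count(n_null, "n_null")
  assert_number(swap_factor, "swap_factor", lower = 0)
  n <- g$n_nodes
  edges <- graph_edges(g)
  real <- cp_lp_of_edges(edges, n)
  niter <- ceiling(swap_factor * g$n_edges)
  c_rand <- numeric(n_null); l_rand <- numeric(n_null)
  for (b in seq_len(n_null)) {
    null_edges <- if (niter == 0) edges else {
      with_seed(derive_seed(seed, 7L, b), {
        .rewire_ms_cpp(edges, n, as.integer(niter))$edges
      })
    }
    m <- cp_lp_of_edges(null_edges, n)
    c_rand[b] <- m$c_p
    l_rand[b] <- m$l_p
  }
  ok <- c_rand > 0 & is.finite(l_rand)
  if (!any(ok)) stop("all null networks degenerate (C_P = 0 or disconnected beyond reach)",
                     call. = FALSE)
  if (any(!ok)) {
    message(sprintf("%d of %d null networks excluded from normalization means",
                    sum(!ok), n_null))
  }
  c_bar <- mean(c_rand[ok]); l_bar <- mean(l_rand[ok])
  gamma <- real$c_p / c_bar
  lam <- real$l_p / l_bar
  list(gamma = gamma, lam = lam, sigma = gamma / lam,
       c_rand = c_bar, l_rand = l_bar,
       n_null = n_null, n_used = sum(ok),
       c_p = real$c_p, l_p = real$l_p)
}
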