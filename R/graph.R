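#' Threshold a connectivity matrix into a binary graph at a given sparsity
#'
#' Sparsity `S` is the ratio of retained edges to the `N(N-1)/2` possible
#' edges. The number of retained edges is `K = round_half_up(S * N(N-1)/2)`;
#' the `K` node pairs with the largest signed Fisher-z values are kept (ties
#' broken lexicographically by `(i, j)`, with a warning when the tie break
#' is actually exercised at the cut). Signed rather than absolute values are
#' ranked: strong negative correlations are never selected. Use
#' `rank_by = "absolute"` for the alternative convention.
#'
#' @param z A `connectivity_matrix` (its `z_matrix` is thresholded) or a
#'   symmetric numeric matrix of edge weights.
#' @param s Sparsity in (0, 1).
#' @param rank_by `"signed"` (default) or `"absolute"`.
#' @return An object of class `binary_graph` with `adjacency` (0/1 matrix),
#'   `n_nodes`, `n_edges`, `sparsity`, `edges`.
#' @export
binarize_by_sparsity <- function(z, s, rank_by = c("signed", "absolute")) {
  rank_by <- match.arg(rank_by)
  m <- if (inherits(z, "connectivity_matrix")) z$z_matrix else as.matrix(z)
  n <- nrow(m)
  assert_number(s, "s", lower = 1e-12, upper = 1 - 1e-12)
  n_pairs <- n * (n - 1) / 2
  k <- floor(s * n_pairs + 0.5)  # round half up
  if (k < 1) stop("sparsity too small: no edges would be retained", call. = FALSE)
  if (k > n_pairs) stop("sparsity too large: more edges than node pairs", call. = FALSE)
  iu <- which(upper.tri(m), arr.ind = TRUE)
  w <- m[iu]
  if (rank_by == "absolute") w <- abs(w)
  ord <- order(-w, iu[, 1], iu[, 2])
  if (k < n_pairs && w[ord[k]] == w[ord[k + 1]]) {
    warning("tie at the sparsity cut broken lexicographically", call. = FALSE)
  }
  sel <- iu[ord[seq_len(k)], , drop = FALSE]
  adj <- matrix(0L, n, n)
  adj[sel] <- 1L
  adj <- adj + t(adj)
  dimnames(adj) <- dimnames(m)
  structure(list(adjacency = adj, n_nodes = n, n_edges = as.integer(k),
                 sparsity = k / n_pairs, edges = unname(sel)),
            class = "binary_graph")
}

#' Construct a binary graph from an adjacency matrix or edge list
#'
#' @param adjacency Symmetric 0/1 matrix with zero diagonal, or `NULL`.
#' @param edges Two-column matrix of node-index pairs (used with `n_nodes`
#'   when `adjacency` is `NULL`).
#' @param n_nodes Number of nodes (required with `edges`).
#' @return A `binary_graph`.
#' @export
binary_graph <- function(adjacency = NULL, edges = NULL, n_nodes = NULL) {
  if (is.null(adjacency)) {
    stopifnot(!is.null(edges), !is.null(n_nodes))
    adjacency <- matrix(0L, n_nodes, n_nodes)
    e <- as.matrix(edges)
    adjacency[e] <- 1L
    adjacency[e[, 2:1, drop = FALSE]] <- 1L
  }
  adjacency <- as.matrix(adjacency)
  n <- nrow(adjacency)
  if (ncol(adjacency) != n || any(adjacency != t(adjacency)) ||
      any(diag(adjacency) != 0) || any(!adjacency %in% c(0, 1))) {
    stop("`adjacency` must be a symmetric 0/1 matrix with zero diagonal",
         call. = FALSE)
  }
  storage.mode(adjacency) <- "integer"
  k <- sum(adjacency) / 2
  structure(list(adjacency = adjacency, n_nodes = n, n_edges = as.integer(k),
                 sparsity = if (n > 1) k / (n * (n - 1) / 2) else 0,
                 edges = which(upper.tri(adjacency) & adjacency == 1L,
                               arr.ind = TRUE, useNames = FALSE)),
            class = "binary_graph")
}

#' @export
print.binary_graph <- function(x, ...) {
  cat(sprintf("<binary_graph> %d nodes, %d edges (sparsity %.3f)\n",
              x$n_nodes, x$n_edges, x$sparsity))
  invisible(x)
}

graph_edges <- function(g) {
  if (!is.null(g$edges)) return(g$edges)
  which(upper.tri(g$adjacency) & g$adjacency == 1L, arr.ind = TRUE,
        useNames = FALSE)
}

#' All-pairs shortest-path census
#'
#' Breadth-first search from every source, returning the matrix of
#' shortest-path lengths `L_ij` (edge counts; `Inf` for unreachable pairs,
#' 0 on the diagonal) and the matrix of shortest-path counts `delta_jk`
#' (number of distinct shortest paths; 0 for unreachable pairs, 1 on the
#' diagonal for the empty path).
#'
#' @param g A `binary_graph`.
#' @return List with `distances` and `path_counts` (both N x N).
#' @export
path_census <- function(g) {
  stopifnot(inherits(g, "binary_graph"))
  cen <- .graph_census_cpp(graph_edges(g), g$n_nodes,
                           want_counts = TRUE, want_betweenness = FALSE)
  list(distances = cen$distances, path_counts = cen$path_counts)
}

#' Global network metrics of a binary graph
#'
#' Computes the clustering coefficient
#' `C_P = (1/N) sum_i E_i / (D_i (D_i - 1) / 2)` (the i-th term is 0 when
#' node i has degree < 2), the global efficiency
#' `E_glob = (1/(N(N-1))) sum_{j != i} 1 / L_ij` (with `1/Inf = 0`), the
#' characteristic path length in its harmonic form `L_P = 1 / E_glob`
#' (`Inf` when `E_glob = 0`), and the local efficiency
#' `E_loc = (1/N) sum_i E_glob(G_i)` where `G_i` is the subgraph induced by
#' the neighbors of node i (0 for neighborhoods with < 2 nodes). With
#' `path_length = "arithmetic"`, `L_P` is instead the arithmetic mean of
#' finite shortest-path lengths over reachable pairs (the alternative
#' convention; the harmonic default is the one whose identity
#' `L_P * E_glob = 1` holds).
#'
#' @param g A `binary_graph`.
#' @param path_length `"harmonic"` (default) or `"arithmetic"`.
#' @return List with `c_p`, `l_p`, `e_glob`, `e_loc`.
#' @export
global_metrics <- function(g, path_length = c("harmonic", "arithmetic")) {
  stopifnot(inherits(g, "binary_graph"))
  path_length <- match.arg(path_length)
  n <- g$n_nodes
  edges <- graph_edges(g)
  c_p <- mean(.local_clustering_cpp(edges, n))
  d <- .graph_census_cpp(edges, n, want_counts = FALSE,
                         want_betweenness = FALSE)$distances
  inv <- 1 / d
  diag(inv) <- 0
  e_glob <- sum(inv) / (n * (n - 1))
  l_p <- if (path_length == "harmonic") {
    if (e_glob > 0) 1 / e_glob else Inf
  } else {
    finite <- is.finite(d) & row(d) != col(d)
    if (any(finite)) mean(d[finite]) else Inf
  }
  e_loc <- mean(.local_efficiency_cpp(edges, n))
  list(c_p = c_p, l_p = l_p, e_glob = e_glob, e_loc = e_loc)
}

#' Nodal centrality metrics of a binary graph
#'
#' Degree `D_nod(i) = sum_j e_ij`; nodal efficiency
#' `E_nod(i) = (1/(N-1)) sum_{j != i} 1 / L_ij` (with `1/Inf = 0`); nodal
#' betweenness `B_nod(i) = sum_{j != i != k} delta_jk(i) / delta_jk` over
#' unordered pairs, unnormalized (Freeman's definition), computed by
#' Brandes' accumulation algorithm (whose output equals exhaustive
#' shortest-path enumeration).
#'
#' @param g A `binary_graph`.
#' @return List with numeric vectors `degree`, `efficiency`, `betweenness`.
#' @export
nodal_metrics <- function(g) {
  stopifnot(inherits(g, "binary_graph"))
  n <- g$n_nodes
  edges <- graph_edges(g)
  cen <- .graph_census_cpp(edges, n, want_counts = FALSE,
                           want_betweenness = TRUE)
  inv <- 1 / cen$distances
  diag(inv) <- 0
  list(degree = as.numeric(tabulate(edges, nbins = n)),
       efficiency = rowSums(inv) / (n - 1),
       betweenness = as.numeric(cen$betweenness))
}
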