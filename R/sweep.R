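#' Sparsity grid for the threshold sweep
#'
#' Defaults to the 33-point grid 0.10, 0.11, ..., 0.42 over which binary
#' networks retain prominent small-world properties.
#'
#' @param s_min,s_max,s_step Grid bounds and step.
#' @return Numeric vector of sparsity values, class `sparsity_grid`.
#' @export
sparsity_grid <- function(s_min = 0.10, s_max = 0.42, s_step = 0.01) {
  assert_number(s_min, "s_min", lower = 1e-12)
  assert_number(s_max, "s_max", upper = 1 - 1e-12)
  assert_number(s_step, "s_step", lower = 1e-12)
  if (s_min > s_max) stop("`s_min` must not exceed `s_max`", call. = FALSE)
  n_step <- floor((s_max - s_min) / s_step + 1e-9)
  grid <- round(s_min + s_step * (0:n_step), 12)
  structure(grid, class = c("sparsity_grid", "numeric"))
}

#' Compute metric curves over a sparsity sweep for one subject
#'
#' For every grid sparsity the connectivity matrix is binarized and the
#' requested metric families computed: `"global"` (C_P, L_P, E_glob,
#' E_loc), `"smallworld"` (gamma, lambda, sigma against `n_null`
#' degree-preserving rewired nulls) and `"nodal"` (degree, efficiency,
#' betweenness per ROI).
#'
#' @param z A `connectivity_matrix` (or plain symmetric matrix).
#' @param grid A [sparsity_grid()].
#' @param metrics Character subset of `c("global", "smallworld", "nodal")`.
#' @param n_null Nulls per threshold for the small-world normalization.
#' @param swap_factor Attempted swaps per edge in each null.
#' @param seed Seed for the null ensembles (one sub-stream per threshold).
#' @param path_length Passed to [global_metrics()].
#' @return List of class `metric_curves`: `grid`; `global` — data.frame
#'   with one row per sparsity and one column per global metric; `nodal` —
#'   list of three sparsity x ROI matrices (`degree`, `efficiency`,
#'   `betweenness`).
#' @export
run_sweep <- function(z, grid = sparsity_grid(),
                      metrics = c("global", "smallworld", "nodal"),
                      n_null = 100, swap_factor = 10, seed = 1L,
                      path_length = "harmonic") {
  metrics <- match.arg(metrics, c("global", "smallworld", "nodal"),
                       several.ok = TRUE)
  n_s <- length(grid)
  labels <- if (inherits(z, "connectivity_matrix")) z$roi_labels else colnames(z)
  n <- if (inherits(z, "connectivity_matrix")) nrow(z$z_matrix) else nrow(z)

  global_cols <- c("c_p", "l_p", "e_glob", "e_loc")[rep(
    "global" %in% metrics, 4)]
  sw_cols <- c("gamma", "lam", "sigma")[rep("smallworld" %in% metrics, 3)]
  glob <- matrix(NA_real_, n_s, length(global_cols) + length(sw_cols),
                 dimnames = list(NULL, c(global_cols, sw_cols)))
  nodal <- NULL
  if ("nodal" %in% metrics) {
    nodal <- list(degree = matrix(NA_real_, n_s, n),
                  efficiency = matrix(NA_real_, n_s, n),
                  betweenness = matrix(NA_real_, n_s, n))
    for (m in names(nodal)) colnames(nodal[[m]]) <- labels
  }

  for (si in seq_len(n_s)) {
    g <- binarize_by_sparsity(z, grid[si])
    if ("global" %in% metrics) {
      gm <- global_metrics(g, path_length = path_length)
      glob[si, c("c_p", "l_p", "e_glob", "e_loc")] <-
        c(gm$c_p, gm$l_p, gm$e_glob, gm$e_loc)
    }
    if ("smallworld" %in% metrics) {
      sw <- normalize_small_world(g, n_null = n_null,
                                  swap_factor = swap_factor,
                                  seed = derive_seed(seed, 13L, si))
      glob[si, c("gamma", "lam", "sigma")] <- c(sw$gamma, sw$lam, sw$sigma)
    }
    if ("nodal" %in% metrics) {
      nm <- nodal_metrics(g)
      nodal$degree[si, ] <- nm$degree
      nodal$efficiency[si, ] <- nm$efficiency
      nodal$betweenness[si, ] <- nm$betweenness
    }
  }
  structure(list(grid = grid,
                 global = if (ncol(glob) > 0) as.data.frame(cbind(sparsity = as.numeric(grid), glob)) else NULL,
                 nodal = nodal),
            class = "metric_curves")
}

#' Area under a metric curve over the sparsity grid
#'
#' Trapezoidal rule, exact for the piecewise-linear curves the sweep
#' produces. Any non-finite value makes the AUC undefined (`NA`, with a
#' warning) rather than silently wrong.
#'
#' @param values Metric values, one per grid point.
#' @param grid The matching [sparsity_grid()].
#' @return A single number (or `NA` for a flagged curve).
#' @export
auc <- function(values, grid) {
  if (length(values) != length(grid)) {
    stop("curve length does not match grid length", call. = FALSE)
  }
  if (length(values) == 1) return(0)
  if (any(!is.finite(values))) {
    warning("non-finite value in metric curve: AUC undefined", call. = FALSE)
    return(NA_real_)
  }
  sum((values[-1] + values[-length(values)]) / 2 * diff(as.numeric(grid)))
}

#' Two-sample permutation test on AUC values
#'
#' Observed statistic is `mean(a) - mean(b)`. The null distribution is
#' built by re-splitting the pooled values into groups of sizes
#' `(length(a), length(b))`: exhaustively when the number of distinct
#' splits is at most `n_perm` (then the p-value is the exact fraction of
#' splits at least as extreme, the observed split being one of them), and
#' by Monte-Carlo resampling otherwise (two-sided p with the add-one
#' correction, never 0). If all pooled values are equal, p = 1.
#'
#' @param a,b Numeric vectors (>= 2 values each).
#' @param n_perm Number of permutations (default 5000).
#' @param seed Integer seed for the Monte-Carlo mode.
#' @return List of class `permutation_result`: `observed_diff`,
#'   `null_diffs`, `p_two_sided`, `method` ("exhaustive" or "monte_carlo").
#' @export
permutation_test <- function(a, b, n_perm = 5000, seed = 1L) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2 || length(b) < 2) {
    stop("need at least 2 values per group", call. = FALSE)
  }
  if (anyNA(a) || anyNA(b)) stop("missing values in AUC inputs", call. = FALSE)
  assert_count(n_perm, "n_perm")
  pool <- c(a, b)
  n_a <- length(a); n <- length(pool)
  observed <- mean(a) - mean(b)
  scale <- max(abs(pool - mean(pool)))
  if (scale == 0) {
    return(structure(list(observed_diff = 0, null_diffs = numeric(0),
                          p_two_sided = 1, method = "degenerate"),
                     class = "permutation_result"))
  }
  tol <- 1e-12 * scale
  total <- sum(pool)
  diff_from_sum_a <- function(sa) sa / n_a - (total - sa) / (n - n_a)
  n_splits <- choose(n, n_a)
  if (n_splits <= n_perm) {
    idx <- utils::combn(n, n_a)
    null_diffs <- diff_from_sum_a(colSums(matrix(pool[idx], nrow = n_a)))
    p <- sum(abs(null_diffs) >= abs(observed) - tol) / n_splits
    method <- "exhaustive"
  } else {
    null_diffs <- with_seed(as.integer(seed), {
      idx <- vapply(seq_len(n_perm), function(i) sample.int(n, n_a),
                    integer(n_a))
      diff_from_sum_a(colSums(matrix(pool[idx], nrow = n_a)))
    })
    p <- (sum(abs(null_diffs) >= abs(observed) - tol) + 1) / (n_perm + 1)
    method <- "monte_carlo"
  }
  structure(list(observed_diff = observed, null_diffs = null_diffs,
                 p_two_sided = p, method = method),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation_result> observed diff %.4g, p = %.4g (%s, %d nulls)\n",
              x$observed_diff, x$p_two_sided, x$method, length(x$null_diffs)))
  invisible(x)
}

#' Permutation tests for every region and nodal metric
#'
#' All region x metric tests share one Monte-Carlo permutation index set
#' (drawn from `seed`), which lets the whole battery be computed as a
#' single matrix product; p-values are two-sided with the add-one
#' correction. When the number of distinct group splits is at most
#' `n_perm`, each test instead falls back to the exact enumeration of
#' [permutation_test()].
#'
#' @param auc_a,auc_b Lists with matrices `degree`, `efficiency`,
#'   `betweenness` of per-subject AUC values (subjects x regions).
#' @param n_perm Permutations (default 5000).
#' @param seed Integer seed for the shared permutation draw.
#' @return data.frame: `region`, `roi`, `metric`, `mean_A`, `mean_B`,
#'   `sd_A`, `sd_B`, `observed_diff`, `p`.
#' @export
nodal_permutation_tests <- function(auc_a, auc_b, n_perm = 5000, seed = 1L) {
  metrics <- c("degree", "efficiency", "betweenness")
  stopifnot(all(metrics %in% names(auc_a)), all(metrics %in% names(auc_b)))
  n_region <- ncol(auc_a$degree)
  labels <- colnames(auc_a$degree)
  if (is.null(labels)) labels <- as.character(seq_len(n_region))
  n_a <- nrow(auc_a$degree); n_b <- nrow(auc_b$degree)
  n <- n_a + n_b
  meta <- data.frame(region = rep(seq_len(n_region), times = length(metrics)),
                     roi = rep(labels, times = length(metrics)),
                     metric = rep(metrics, each = n_region),
                     stringsAsFactors = FALSE)
  if (anyNA(unlist(auc_a)) || anyNA(unlist(auc_b))) {
    stop("missing values in nodal AUC inputs", call. = FALSE)
  }
  if (choose(n, n_a) <= n_perm) {
    p_obs <- t(mapply(function(j, m) {
      pt <- permutation_test(auc_a[[m]][, j], auc_b[[m]][, j], n_perm, seed)
      c(pt$observed_diff, pt$p_two_sided)
    }, meta$region, meta$metric))
    observed <- p_obs[, 1]; pvals <- p_obs[, 2]
  } else {
    v <- rbind(do.call(cbind, auc_a[metrics]), do.call(cbind, auc_b[metrics]))
    observed <- colMeans(v[seq_len(n_a), , drop = FALSE]) -
      colMeans(v[seq.int(n_a + 1, n), , drop = FALSE])
    ind <- with_seed(as.integer(seed), {
      m <- matrix(0, n_perm, n)
      for (r in seq_len(n_perm)) m[r, sample.int(n, n_a)] <- 1
      m
    })
    sum_a <- ind %*% v
    totals <- matrix(colSums(v), n_perm, ncol(v), byrow = TRUE)
    null_diffs <- sum_a / n_a - (totals - sum_a) / n_b
    scale <- apply(v, 2, function(x) max(abs(x - mean(x))))
    tol <- 1e-12 * scale
    exceed <- colSums(abs(null_diffs) >=
                        matrix(abs(observed) - tol, n_perm, ncol(v), byrow = TRUE))
    pvals <- ifelse(scale == 0, 1, (exceed + 1) / (n_perm + 1))
    observed[scale == 0] <- 0
  }
  data.frame(meta[, c("region", "roi", "metric")],
             mean_A = apply(do.call(cbind, auc_a[metrics]), 2, mean),
             mean_B = apply(do.call(cbind, auc_b[metrics]), 2, mean),
             sd_A = apply(do.call(cbind, auc_a[metrics]), 2, stats::sd),
             sd_B = apply(do.call(cbind, auc_b[metrics]), 2, stats::sd),
             observed_diff = observed, p = pvals,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Flag regions changed in at least one nodal metric
#'
#' A region is flagged when the minimum permutation p over its three nodal
#' metrics (degree, efficiency, betweenness) is below `alpha` — the
#' "significant in at least one nodal metric" rule. Note this union over
#' three tests inflates the per-region type-I rate beyond `alpha`; the
#' per-metric p-values are returned so stricter control can be applied.
#'
#' @param nodal_results Output of [nodal_permutation_tests()].
#' @param alpha Per-metric significance level (default 0.05).
#' @return data.frame sorted by region index: `region`, `roi`, per-metric
#'   p-values and directions (`"A>B"` / `"A<B"`), `min_p`, `flagged`.
#' @export
flag_changed_regions <- function(nodal_results, alpha = 0.05) {
  assert_number(alpha, "alpha", lower = 0, upper = 1)
  sp <- split(nodal_results, nodal_results$region)
  out <- do.call(rbind, lapply(sp, function(d) {
    d <- d[match(c("degree", "efficiency", "betweenness"), d$metric), ]
    dirs <- ifelse(d$observed_diff >= 0, "A>B", "A<B")
    data.frame(region = d$region[1], roi = d$roi[1],
               p_degree = d$p[1], p_efficiency = d$p[2], p_betweenness = d$p[3],
               dir_degree = dirs[1], dir_efficiency = dirs[2],
               dir_betweenness = dirs[3],
               min_p = min(d$p), flagged = min(d$p) < alpha,
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$region), ]
  rownames(out) <- NULL
  out
}

#' Correlate regional AUC values with training duration
#'
#' Pearson correlation per region between subjects' AUC values and their
#' training durations, with Bonferroni family correction over the number
#' of regions (`alpha_family / n_regions`, the `0.05/110` rule at
#' defaults). Regions passing the uncorrected 0.05 level are also marked.
#'
#' @param auc_by_region Subjects x regions matrix of AUC values.
#' @param training_years Training durations (one per subject; at least 3
#'   non-missing).
#' @param alpha_family Family-wise alpha (default 0.05).
#' @return data.frame: `region`, `roi`, `r`, `p`, `significant_bonferroni`,
#'   `significant_uncorrected`.
#' @export
correlate_training <- function(auc_by_region, training_years,
                               alpha_family = 0.05) {
  auc_by_region <- as.matrix(auc_by_region)
  keep <- !is.na(training_years)
  if (sum(keep) < 3) stop("need >= 3 subjects with training values", call. = FALSE)
  x <- training_years[keep]
  m <- auc_by_region[keep, , drop = FALSE]
  n_region <- ncol(m)
  labels <- colnames(m)
  if (is.null(labels)) labels <- as.character(seq_len(n_region))
  res <- lapply(seq_len(n_region), function(j) {
    y <- m[, j]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      warning(sprintf("zero variance in region %d: correlation undefined", j),
              call. = FALSE)
      return(c(NaN, NaN))
    }
    ct <- stats::cor.test(x, y)
    c(unname(ct$estimate), ct$p.value)
  })
  res <- do.call(rbind, res)
  data.frame(region = seq_len(n_region), roi = labels,
             r = res[, 1], p = res[, 2],
             significant_bonferroni = res[, 2] < alpha_family / n_region,
             significant_uncorrected = res[, 2] < 0.05,
             stringsAsFactors = FALSE)
}
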