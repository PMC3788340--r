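#' Specify a synthetic two-group resting-state cohort
#'
#' Builds the parameter object consumed by [generate_cohort()]. The defaults
#' emulate the study design the package targets: 17 experts (group A) and 16
#' novices (group B), 110 ROIs, 120 volumes at TR = 2.34 s of which the first
#' 4 are later discarded, and expert training durations of about
#' 12.47 +/- 1.50 years. The interregional covariance of the simulated BOLD
#' signal is planted on a Watts-Strogatz small-world graph (ring lattice with
#' `neighbors_k` neighbors per node, rewired with probability `rewire_prob`)
#' so that thresholded networks sit in the small-world regime; a localized
#' group difference is planted by incrementing, for group A only, the
#' covariance of edges among `effect_rois` by `effect_delta`.
#'
#' @param n_group_a,n_group_b Group sizes (experts / novices).
#' @param n_rois Number of ROIs (network nodes).
#' @param n_volumes Number of acquired volumes per subject.
#' @param n_discard Initial volumes the preprocessing stage will discard
#'   (recorded here so the manifest is self-describing; the generator returns
#'   all `n_volumes` rows).
#' @param tr_seconds Repetition time in seconds.
#' @param base_graph List with `neighbors_k` (even count of lattice
#'   neighbors per node), `rewire_prob` (Watts-Strogatz rewiring
#'   probability) and `graph_seed` (seed of the rewiring draw). The
#'   backbone plays the role of anatomy: it is deterministic in
#'   `graph_seed` and deliberately *not* tied to the cohort `seed`, so
#'   regenerating a cohort with a new seed resamples subjects from the
#'   same population rather than changing the population itself.
#' @param edge_weight Covariance placed on every base-graph edge.
#' @param diag_boost Value added to the covariance diagonal.
#' @param effect_rois Integer ROI indices carrying the planted group effect.
#' @param effect_delta Additive covariance increment applied, in group A
#'   only, to base-graph edges with both endpoints in `effect_rois`.
#' @param ar_coefficient AR(1) temporal smoothing coefficient in `[0, 1)`.
#' @param nuisance List with nonnegative `global_amp`, `drift_amp`,
#'   `motion_amp`: amplitudes of the shared global random-walk signal, the
#'   linear drift, and the six motion-like low-frequency regressors.
#' @param training_mean_years,training_sd_years Mean and SD of the
#'   truncated-normal (at 0) training durations drawn for group A.
#' @param seed Master seed; every random draw in the cohort derives from it.
#'
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_group_a = 17, n_group_b = 16,
                        n_rois = 110, n_volumes = 120, n_discard = 4,
                        tr_seconds = 2.34,
                        base_graph = list(neighbors_k = 10, rewire_prob = 0.1,
                                          graph_seed = 7L),
                        edge_weight = 0.25, diag_boost = 1.5,
                        effect_rois = 106:110, effect_delta = 0.8,
                        ar_coefficient = 0.3,
                        nuisance = list(global_amp = 0.5, drift_amp = 0.5,
                                        motion_amp = 0.2),
                        training_mean_years = 12.47,
                        training_sd_years = 1.50,
                        seed = 1L) {
  assert_count(n_group_a, "n_group_a"); assert_count(n_group_b, "n_group_b")
  assert_count(n_rois, "n_rois", min = 3)
  assert_count(n_volumes, "n_volumes")
  assert_count(n_discard, "n_discard", min = 0)
  if (n_volumes <= n_discard) stop("`n_volumes` must exceed `n_discard`", call. = FALSE)
  assert_number(tr_seconds, "tr_seconds", lower = 1e-6)
  assert_count(base_graph$neighbors_k, "base_graph$neighbors_k", min = 2)
  if (base_graph$neighbors_k %% 2 != 0) {
    stop("`base_graph$neighbors_k` must be even", call. = FALSE)
  }
  if (base_graph$neighbors_k >= n_rois) {
    stop("`base_graph$neighbors_k` must be smaller than `n_rois`", call. = FALSE)
  }
  assert_number(base_graph$rewire_prob, "base_graph$rewire_prob", 0, 1)
  if (is.null(base_graph$graph_seed)) base_graph$graph_seed <- 7L
  assert_number(edge_weight, "edge_weight", lower = 1e-12)
  assert_number(diag_boost, "diag_boost", lower = 1e-12)
  effect_rois <- as.integer(effect_rois)
  if (length(effect_rois) > 0 &&
      (anyNA(effect_rois) || any(effect_rois < 1) || any(effect_rois > n_rois) ||
       anyDuplicated(effect_rois))) {
    stop("`effect_rois` must be unique indices in 1..n_rois", call. = FALSE)
  }
  assert_number(effect_delta, "effect_delta")
  assert_number(ar_coefficient, "ar_coefficient", 0, 1 - 1e-9)
  for (nm in c("global_amp", "drift_amp", "motion_amp")) {
    assert_number(nuisance[[nm]], paste0("nuisance$", nm), lower = 0)
  }
  assert_number(training_mean_years, "training_mean_years")
  assert_number(training_sd_years, "training_sd_years", lower = 0)
  spec <- list(
    n_group_a = as.integer(n_group_a), n_group_b = as.integer(n_group_b),
    n_rois = as.integer(n_rois), n_volumes = as.integer(n_volumes),
    n_discard = as.integer(n_discard), tr_seconds = tr_seconds,
    base_graph = list(neighbors_k = as.integer(base_graph$neighbors_k),
                      rewire_prob = base_graph$rewire_prob,
                      graph_seed = as.integer(base_graph$graph_seed)),
    edge_weight = edge_weight, diag_boost = diag_boost,
    effect_rois = effect_rois, effect_delta = effect_delta,
    ar_coefficient = ar_coefficient,
    nuisance = nuisance[c("global_amp", "drift_amp", "motion_amp")],
    training_mean_years = training_mean_years,
    training_sd_years = training_sd_years,
    seed = as.integer(seed)
  )
  class(spec) <- "cohort_spec"
  spec
}

# Watts-Strogatz construction: ring lattice with neighbors_k nearest
# neighbors per node, each lattice edge rewired with probability
# rewire_prob to a uniformly chosen non-adjacent endpoint. Deterministic
# in base_graph$graph_seed, independent of the cohort seed.
base_graph_adjacency <- function(spec) {
  n <- spec$n_rois
  k2 <- spec$base_graph$neighbors_k / 2
  A <- matrix(0L, n, n)
  for (d in seq_len(k2)) {
    j <- (seq_len(n) - 1 + d) %% n + 1
    A[cbind(seq_len(n), j)] <- 1L
    A[cbind(j, seq_len(n))] <- 1L
  }
  p <- spec$base_graph$rewire_prob
  if (p > 0) {
    with_seed(derive_seed(spec$base_graph$graph_seed, 101L), {
      for (d in seq_len(k2)) {
        for (i in seq_len(n)) {
          j <- (i - 1 + d) %% n + 1
          if (A[i, j] == 1L && stats::runif(1) < p) {
            candidates <- which(A[i, ] == 0L & seq_len(n) != i)
            if (length(candidates) > 0) {
              m <- candidates[sample.int(length(candidates), 1)]
              A[i, j] <- A[j, i] <- 0L
              A[i, m] <- A[m, i] <- 1L
            }
          }
        }
      }
    })
  }
  A
}

#' Build the interregional covariance for one group
#'
#' The covariance is `edge_weight * A + diag_boost * I`, where `A` is the
#' adjacency matrix of the spec's rewired ring lattice (shared by both
#' groups). For group `"A"` only, entries whose endpoints both lie in
#' `effect_rois` and that are base-graph edges are incremented by
#' `effect_delta`. The result is checked for positive definiteness.
#'
#' @param spec A [cohort_spec()].
#' @param group `"A"` or `"B"`.
#' @return A symmetric positive-definite `n_rois` x `n_rois` matrix.
#' @export
build_group_covariance <- function(spec, group = c("A", "B")) {
  stopifnot(inherits(spec, "cohort_spec"))
  group <- match.arg(group)
  A <- base_graph_adjacency(spec)
  sigma <- spec$edge_weight * A
  diag(sigma) <- diag(sigma) + spec$diag_boost
  if (group == "A" && length(spec$effect_rois) >= 2 && spec$effect_delta != 0) {
    idx <- spec$effect_rois
    sigma[idx, idx] <- sigma[idx, idx] + spec$effect_delta * A[idx, idx]
  }
  ev_min <- min(eigen(sigma, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min <= 0) {
    stop(sprintf(
      "constructed covariance is not positive-definite (smallest eigenvalue %.6g); reduce edge_weight/effect_delta or raise diag_boost",
      ev_min), call. = FALSE)
  }
  sigma
}

#' Simulate one subject's ROI time series
#'
#' Draws `n_volumes` multivariate-normal rows with the given covariance,
#' applies AR(1) temporal smoothing
#' `x_t <- phi * x_{t-1} + sqrt(1 - phi^2) * x_t`, and adds shared nuisance
#' components: a global standardized random-walk signal (`global_amp`, added
#' to every ROI), a linear drift (`drift_amp`), and six motion-like
#' random-walk regressors with ROI-specific loadings (`motion_amp`). The
#' regressors are stored in the returned object (`$nuisance`) so the
#' preprocessing stage can regress exactly the true confounds. All
#' `n_volumes` rows are returned; discarding initial volumes is the
#' pipeline's job.
#'
#' @param cov Positive-definite covariance matrix (N x N).
#' @param spec A [cohort_spec()].
#' @param subject_seed Integer seed; the draw is fully reproducible from it.
#' @param subject_id,group,training_years Metadata carried on the object.
#' @return An object of class `subject_ts` with fields `subject_id`,
#'   `group`, `data` (T x N matrix), `tr_seconds`, `training_years`,
#'   `nuisance` (T x 8 regressor matrix).
#' @export
simulate_subject <- function(cov, spec, subject_seed,
                             subject_id = "sub", group = "A",
                             training_years = NA_real_) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- ncol(cov)
  t_len <- spec$n_volumes
  ch <- tryCatch(chol(cov), error = function(e) {
    stop("`cov` must be positive-definite", call. = FALSE)
  })
  with_seed(as.integer(subject_seed), {
    x <- matrix(stats::rnorm(t_len * n), t_len, n) %*% ch
    phi <- spec$ar_coefficient
    if (phi > 0) {
      w <- sqrt(1 - phi^2)
      for (t in 2:t_len) x[t, ] <- phi * x[t - 1, ] + w * x[t, ]
    }
    rw <- function() {
      g <- cumsum(stats::rnorm(t_len))
      g <- g - mean(g)
      s <- stats::sd(g)
      if (s > 0) g / s else g
    }
    global_sig <- rw()
    drift <- seq(-1, 1, length.out = t_len)
    motion <- sapply(seq_len(6), function(k) rw())
    amps <- spec$nuisance
    if (amps$global_amp > 0) x <- x + amps$global_amp * global_sig
    if (amps$drift_amp > 0) x <- x + amps$drift_amp * drift
    if (amps$motion_amp > 0) {
      loadings <- matrix(stats::rnorm(6 * n), 6, n)
      x <- x + amps$motion_amp * (motion %*% loadings)
    }
    nuis <- cbind(global = global_sig, drift = drift, motion)
    colnames(nuis) <- c("global", "drift", paste0("motion", 1:6))
    colnames(x) <- paste0("ROI", seq_len(n))
    structure(list(subject_id = subject_id, group = group, data = x,
                   tr_seconds = spec$tr_seconds,
                   training_years = training_years, nuisance = nuis),
              class = "subject_ts")
  })
}

#' @export
print.subject_ts <- function(x, ...) {
  cat(sprintf("<subject_ts> %s  group %s  %d volumes x %d ROIs  TR %.3g s\n",
              x$subject_id, x$group, nrow(x$data), ncol(x$data), x$tr_seconds))
  invisible(x)
}

#' Generate a synthetic two-group cohort
#'
#' Simulates every subject of the spec (group A then group B) with
#' per-subject seeds derived deterministically from `spec$seed`. Group-A
#' subjects receive a training duration drawn from
#' `Normal(training_mean_years, training_sd_years)` truncated at zero.
#'
#' @param spec A [cohort_spec()].
#' @return A list of class `cohort` with `subjects` (list of `subject_ts`),
#'   `manifest` (data.frame: subject_id, group, training_years, seed) and
#'   `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  cov_a <- build_group_covariance(spec, "A")
  cov_b <- build_group_covariance(spec, "B")
  n_total <- spec$n_group_a + spec$n_group_b
  groups <- rep(c("A", "B"), c(spec$n_group_a, spec$n_group_b))
  ids <- sprintf("sub-%s%02d", groups,
                 c(seq_len(spec$n_group_a), seq_len(spec$n_group_b)))
  training <- with_seed(derive_seed(spec$seed, 202L), {
    tr <- rep(NA_real_, n_total)
    for (i in which(groups == "A")) {
      repeat {
        y <- stats::rnorm(1, spec$training_mean_years, spec$training_sd_years)
        if (y > 0) break
      }
      tr[i] <- y
    }
    tr
  })
  seeds <- vapply(seq_len(n_total), function(i) derive_seed(spec$seed, 303L, i),
                  integer(1))
  subjects <- lapply(seq_len(n_total), function(i) {
    simulate_subject(if (groups[i] == "A") cov_a else cov_b, spec, seeds[i],
                     subject_id = ids[i], group = groups[i],
                     training_years = training[i])
  })
  manifest <- data.frame(subject_id = ids, group = groups,
                         training_years = training, seed = seeds,
                         stringsAsFactors = FALSE)
  structure(list(subjects = subjects, manifest = manifest, spec = spec),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d subjects (%d A / %d B), %d ROIs, %d volumes\n",
              length(x$subjects), sum(x$manifest$group == "A"),
              sum(x$manifest$group == "B"), x$spec$n_rois, x$spec$n_volumes))
  invisible(x)
}
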