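#' Preprocessing configuration
#'
#' @param discard_initial Initial volumes to drop (default 4).
#' @param band_low_hz,band_high_hz Band-pass edges in Hz (default
#'   0.01-0.08, the canonical resting-state band).
#' @param nuisance_regressors Optional T x K regressor matrix; either
#'   full-length (rows matching the raw series, trimmed along with the
#'   data) or already matching the post-discard length.
#' @param include_global_signal Regress out the mean signal across ROIs
#'   (ROI-level analog of global signal regression)? Default `TRUE`.
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(discard_initial = 4,
                              band_low_hz = 0.01, band_high_hz = 0.08,
                              nuisance_regressors = NULL,
                              include_global_signal = TRUE) {
  assert_count(discard_initial, "discard_initial", min = 0)
  assert_number(band_low_hz, "band_low_hz", lower = 0)
  assert_number(band_high_hz, "band_high_hz", lower = 0)
  if (band_low_hz >= band_high_hz) {
    stop("`band_low_hz` must be below `band_high_hz`", call. = FALSE)
  }
  if (!is.null(nuisance_regressors)) {
    nuisance_regressors <- as.matrix(nuisance_regressors)
  }
  structure(list(discard_initial = as.integer(discard_initial),
                 band_low_hz = band_low_hz, band_high_hz = band_high_hz,
                 nuisance_regressors = nuisance_regressors,
                 include_global_signal = isTRUE(include_global_signal)),
            class = "preprocess_config")
}

# Ideal (brick-wall) frequency-domain band-pass: DFT coefficients at
# frequencies outside [low, high] are zeroed, conjugate symmetry preserved
# by construction of the frequency axis.
ideal_bandpass <- function(x, tr, low, high) {
  t_len <- nrow(x)
  freqs <- seq(0, t_len - 1) / (t_len * tr)
  freqs <- pmin(freqs, 1 / tr - freqs)  # fold to [0, Nyquist]
  keep <- freqs >= low & freqs <= high
  xf <- stats::mvfft(x)
  xf[!keep, ] <- 0
  Re(stats::mvfft(xf, inverse = TRUE)) / t_len
}

#' Preprocess one subject's ROI time series
#'
#' Applies, in order: (1) discard the first `discard_initial` volumes,
#' (2) per-ROI removal of the ordinary-least-squares linear trend
#' (intercept and slope), (3) an ideal discrete-Fourier band-pass filter,
#' (4) least-squares regression of nuisance signals (the configured
#' regressors plus, when `include_global_signal`, the mean across ROIs),
#' keeping the residuals. If `ts` carries stored nuisance regressors (as
#' produced by [simulate_subject()]) and the config has none, the stored
#' ones are used.
#'
#' @param ts A `subject_ts`.
#' @param cfg A [preprocess_config()].
#' @return A `subject_ts` with preprocessed `data`.
#' @export
preprocess <- function(ts, cfg = preprocess_config()) {
  stopifnot(inherits(ts, "subject_ts"), inherits(cfg, "preprocess_config"))
  x <- ts$data
  t_raw <- nrow(x)
  if (cfg$discard_initial >= t_raw) {
    stop("`discard_initial` must be smaller than the number of volumes",
         call. = FALSE)
  }
  nyquist <- 1 / (2 * ts$tr_seconds)
  if (cfg$band_high_hz >= nyquist) {
    stop(sprintf("band_high_hz (%.4g) must be below the Nyquist frequency (%.4g Hz)",
                 cfg$band_high_hz, nyquist), call. = FALSE)
  }
  keep_rows <- seq.int(cfg$discard_initial + 1, t_raw)
  x <- x[keep_rows, , drop = FALSE]
  t_len <- nrow(x)

  # detrend: residuals of per-column OLS on (1, t)
  tt <- seq_len(t_len)
  basis <- cbind(1, tt)
  x <- stats::lm.fit(basis, x)$residuals

  x <- ideal_bandpass(x, ts$tr_seconds, cfg$band_low_hz, cfg$band_high_hz)

  reg <- cfg$nuisance_regressors
  if (is.null(reg) && !is.null(ts$nuisance)) reg <- ts$nuisance
  design <- NULL
  if (!is.null(reg)) {
    reg <- as.matrix(reg)
    if (nrow(reg) == t_raw) {
      reg <- reg[keep_rows, , drop = FALSE]
    } else if (nrow(reg) != t_len) {
      stop(sprintf("nuisance regressors have %d rows; expected %d (full) or %d (post-discard)",
                   nrow(reg), t_raw, t_len), call. = FALSE)
    }
    design <- reg
  }
  if (cfg$include_global_signal) {
    design <- cbind(design, global_signal = rowMeans(x))
  }
  if (!is.null(design)) {
    design <- cbind(intercept = 1, design)
    x <- stats::lm.fit(design, x)$residuals
  }
  out <- ts
  out$data <- x
  out$nuisance <- NULL
  out$preprocessed <- TRUE
  out
}

#' Fisher r-to-z transform
#'
#' `artanh(r) = 0.5 * log((1 + r) / (1 - r))`, the variance-stabilizing
#' transform applied to Pearson correlations before parametric comparison.
#' Applied elementwise; for matrices the (zero) diagonal is left at 0.
#'
#' @param r Correlation value(s) with `|r| < 1` (diagonal entries of a
#'   square matrix may be anything; they are reset to 0).
#' @return Transformed value(s) of the same shape.
#' @export
fisher_z <- function(r) {
  if (is.matrix(r) && nrow(r) == ncol(r)) {
    off <- r[row(r) != col(r)]
    if (any(abs(off) >= 1)) {
      stop("fisher_z is undefined for |r| >= 1", call. = FALSE)
    }
    z <- atanh(r * (row(r) != col(r)))
    diag(z) <- 0
    return(z)
  }
  if (any(abs(r) >= 1)) stop("fisher_z is undefined for |r| >= 1", call. = FALSE)
  atanh(r)
}

#' Interregional connectivity matrix
#'
#' Pearson correlations between all ROI pairs of a (preprocessed) subject
#' time series, with the Fisher-z transform applied elementwise. The
#' diagonal is set to 0 by convention.
#'
#' @param ts A `subject_ts`.
#' @return An object of class `connectivity_matrix` with `r_matrix`,
#'   `z_matrix` and `roi_labels`.
#' @export
correlation_matrix <- function(ts) {
  stopifnot(inherits(ts, "subject_ts"))
  x <- ts$data
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    bad <- colnames(x)[sds == 0]
    if (is.null(bad)) bad <- which(sds == 0)
    stop(sprintf("zero-variance ROI column(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  r <- stats::cor(x)
  diag(r) <- 0
  r <- (r + t(r)) / 2
  if (any(abs(r[row(r) != col(r)]) >= 1)) {
    warning("perfectly correlated ROI pair(s): Fisher z is infinite there",
            call. = FALSE)
    z <- atanh(pmin(pmax(r, -1), 1) * (row(r) != col(r)))
    z[abs(r) >= 1 & row(r) != col(r)] <- sign(r[abs(r) >= 1 & row(r) != col(r)]) * Inf
    diag(z) <- 0
  } else {
    z <- fisher_z(r)
  }
  structure(list(r_matrix = r, z_matrix = z,
                 roi_labels = colnames(x), subject_id = ts$subject_id,
                 group = ts$group),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("<connectivity_matrix> %d ROIs (subject %s)\n",
              nrow(x$r_matrix), x$subject_id %||% "?"))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Seed-based functional-connectivity map
#'
#' Averages the signal across the seed ROI columns and returns the Fisher-z
#' transformed Pearson correlation of that seed signal with every non-seed
#' ROI.
#'
#' @param ts A (preprocessed) `subject_ts`.
#' @param seed_rois Integer indices of the seed ROI set.
#' @return An object of class `seed_fc_map` with `seed_label`, `roi_labels`
#'   (non-seed) and `z_values`.
#' @export
seed_fc_map <- function(ts, seed_rois) {
  stopifnot(inherits(ts, "subject_ts"))
  n <- ncol(ts$data)
  seed_rois <- as.integer(seed_rois)
  if (length(seed_rois) == 0 || any(seed_rois < 1) || any(seed_rois > n)) {
    stop("`seed_rois` must be a nonempty set of indices in 1..N", call. = FALSE)
  }
  seed_sig <- rowMeans(ts$data[, seed_rois, drop = FALSE])
  if (stats::sd(seed_sig) == 0) stop("seed signal has zero variance", call. = FALSE)
  targets <- setdiff(seq_len(n), seed_rois)
  r <- vapply(targets, function(j) stats::cor(seed_sig, ts$data[, j]), numeric(1))
  labels <- colnames(ts$data)[targets]
  if (is.null(labels)) labels <- as.character(targets)
  structure(list(seed_label = paste(colnames(ts$data)[seed_rois] %||%
                                      as.character(seed_rois), collapse = "+"),
                 roi_labels = labels, roi_index = targets,
                 z_values = fisher_z(r), subject_id = ts$subject_id),
            class = "seed_fc_map")
}

#' Group comparison of seed-FC maps
#'
#' Per non-seed ROI: pooled-variance two-sample Student t between the two
#' groups' Fisher-z values, two-sided p, Benjamini-Hochberg q across ROIs,
#' plus within-group one-sample t statistics against zero. A zero-variance
#' ROI yields `NaN` statistics with a warning rather than an error, so one
#' degenerate ROI cannot kill a cohort run.
#'
#' @param maps_a,maps_b Lists of [seed_fc_map()] objects (same ROI order).
#' @return A data.frame with one row per ROI: `roi`, `mean_A`, `mean_B`,
#'   `t`, `p_uncorrected`, `q_fdr`, `t_one_sample_A`, `p_one_sample_A`,
#'   `t_one_sample_B`, `p_one_sample_B`.
#' @export
group_fc_tests <- function(maps_a, maps_b) {
  if (length(maps_a) < 2 || length(maps_b) < 2) {
    stop("need at least 2 subjects per group", call. = FALSE)
  }
  za <- do.call(rbind, lapply(maps_a, function(m) m$z_values))
  zb <- do.call(rbind, lapply(maps_b, function(m) m$z_values))
  if (ncol(za) != ncol(zb)) stop("map lengths differ between groups", call. = FALSE)
  n_a <- nrow(za); n_b <- nrow(zb)
  mean_a <- colMeans(za); mean_b <- colMeans(zb)
  var_a <- apply(za, 2, stats::var); var_b <- apply(zb, 2, stats::var)
  sp2 <- ((n_a - 1) * var_a + (n_b - 1) * var_b) / (n_a + n_b - 2)
  se <- sqrt(sp2 * (1 / n_a + 1 / n_b))
  tstat <- (mean_a - mean_b) / se
  degenerate <- se == 0
  if (any(degenerate)) {
    tstat[degenerate] <- NaN
    warning(sprintf("%d ROI(s) with zero pooled variance: t/p set to NaN",
                    sum(degenerate)), call. = FALSE)
  }
  df <- n_a + n_b - 2
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  one_sample <- function(z, m, v, n) {
    t1 <- m / sqrt(v / n)
    list(t = t1, p = 2 * stats::pt(abs(t1), n - 1, lower.tail = FALSE))
  }
  os_a <- one_sample(za, mean_a, var_a, n_a)
  os_b <- one_sample(zb, mean_b, var_b, n_b)
  labels <- maps_a[[1]]$roi_labels
  data.frame(roi = labels, mean_A = mean_a, mean_B = mean_b,
             t = tstat, p_uncorrected = p,
             q_fdr = stats::p.adjust(p, method = "BH"),
             t_one_sample_A = os_a$t, p_one_sample_A = os_a$p,
             t_one_sample_B = os_b$t, p_one_sample_B = os_b$p,
             row.names = NULL, stringsAsFactors = FALSE)
}
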