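test_that("detrending zeroes a constant column", {
  set.seed(1)
  x <- cbind(rep(3.7, 100), rnorm(100))
  ts <- make_ts(x)
  out <- preprocess(ts, preprocess_config(discard_initial = 0,
                                          include_global_signal = FALSE))
  expect_lt(max(abs(out$data[, 1])), 1e-10)
})

test_that("ideal band-pass keeps in-band and kills out-of-band sinusoids", {
  tr <- 2.34
  t_len <- 116
  tt <- (seq_len(t_len) - 1) * tr
  gain <- function(freq) {
    x <- cbind(sin(2 * pi * freq * tt))
    y <- netsweep:::ideal_bandpass(x, tr, 0.01, 0.08)
    sqrt(mean(y^2)) / sqrt(mean(x^2))
  }
  # bin-aligned frequencies (k / (T * TR)): ~0.0405 Hz in band, ~0.151 Hz out
  expect_gt(gain(11 / (t_len * tr)), 0.95)
  expect_lt(gain(11 / (t_len * tr)), 1.05)
  expect_lt(gain(41 / (t_len * tr)), 0.05)
})

test_that("the ideal band-pass filter is idempotent", {
  set.seed(2)
  x <- matrix(rnorm(116 * 5), 116, 5)
  once <- netsweep:::ideal_bandpass(x, 2.34, 0.01, 0.08)
  twice <- netsweep:::ideal_bandpass(once, 2.34, 0.01, 0.08)
  expect_lt(max(abs(twice - once)), 1e-10)
})

test_that("a band edge above Nyquist is rejected", {
  ts <- make_ts(matrix(rnorm(200), 100, 2), tr = 2.34)
  expect_error(preprocess(ts, preprocess_config(discard_initial = 0,
                                                band_high_hz = 0.25)),
               "Nyquist")
})

test_that("residuals are orthogonal to every nuisance regressor", {
  set.seed(3)
  t_raw <- 120
  x <- matrix(rnorm(t_raw * 8), t_raw, 8)
  reg <- matrix(rnorm(t_raw * 3), t_raw, 3)
  ts <- make_ts(x)
  out <- preprocess(ts, preprocess_config(discard_initial = 4,
                                          nuisance_regressors = reg,
                                          include_global_signal = TRUE))
  kept <- reg[-(1:4), , drop = FALSE]
  expect_lt(max(abs(crossprod(kept, out$data))), 1e-8)
})

test_that("regressor length must match the series before or after discarding", {
  ts <- make_ts(matrix(rnorm(120 * 3), 120, 3))
  bad <- matrix(rnorm(100 * 2), 100, 2)
  expect_error(preprocess(ts, preprocess_config(nuisance_regressors = bad)),
               "regressors")
})

test_that("preprocessing steps run in the documented order", {
  # a linear trend present only in the discarded rows must not leak into
  # the detrending fit
  t_raw <- 60
  x <- matrix(rnorm(t_raw * 2), t_raw, 2)
  x[1:4, 1] <- x[1:4, 1] + 100
  ts <- make_ts(x, tr = 1)
  out <- preprocess(ts, preprocess_config(discard_initial = 4,
                                          band_low_hz = 0.01,
                                          band_high_hz = 0.4,
                                          include_global_signal = FALSE))
  ref <- preprocess(make_ts(x[-(1:4), , drop = FALSE], tr = 1),
                    preprocess_config(discard_initial = 0,
                                      band_low_hz = 0.01, band_high_hz = 0.4,
                                      include_global_signal = FALSE))
  expect_equal(out$data, ref$data)
})

test_that("correlation matrix matches the textbook Pearson formula", {
  x <- cbind(c(1, 2, 4, 3, 7, 5), c(2, 1, 5, 4, 8, 2),
             c(9, 7, 5, 3, 1, 0), c(0.5, 2.5, 1.5, 4.5, 3.5, 6.5))
  cm <- correlation_matrix(make_ts(x))
  for (i in 1:3) {
    for (j in (i + 1):4) {
      xi <- x[, i] - mean(x[, i]); xj <- x[, j] - mean(x[, j])
      r_direct <- sum(xi * xj) / sqrt(sum(xi^2) * sum(xj^2))
      expect_equal(cm$r_matrix[i, j], r_direct, tolerance = 1e-12)
      expect_equal(cm$z_matrix[i, j], atanh(r_direct), tolerance = 1e-12)
    }
  }
  expect_equal(diag(cm$r_matrix), rep(0, 4))
  expect_equal(cm$r_matrix, t(cm$r_matrix))
})

test_that("correlations are invariant to affine rescaling and reflect sign", {
  set.seed(4)
  x <- matrix(rnorm(50 * 3), 50, 3)
  x <- cbind(x, -x[, 1] + 0.5)          # negated copy of column 1
  cm <- suppressWarnings(correlation_matrix(make_ts(x)))
  expect_equal(cm$r_matrix[1, 4], -1)
  y <- x
  y[, 2] <- 3.5 * y[, 2] + 11
  cm2 <- suppressWarnings(correlation_matrix(make_ts(y)))
  expect_equal(cm$r_matrix[2, 3], cm2$r_matrix[2, 3], tolerance = 1e-12)
  # identical columns: r = 1, infinite z flagged
  z <- cbind(x[, 1], x[, 1], x[, 2])
  expect_warning(cmz <- correlation_matrix(make_ts(z)), "infinite")
  expect_equal(cmz$r_matrix[1, 2], 1)
  expect_equal(cmz$z_matrix[1, 2], Inf)
})

test_that("zero-variance ROI columns are rejected by name", {
  x <- matrix(rnorm(40), 20, 2)
  x <- cbind(x, 0)
  colnames(x) <- c("a", "b", "dead")
  expect_error(correlation_matrix(make_ts(x)), "dead")
})

test_that("fisher z matches its closed forms and is odd", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(tanh(1)), 1, tolerance = 1e-4)
  expect_equal(fisher_z(-0.5), -0.5493061, tolerance = 1e-5)
  r <- seq(-0.9, 0.9, by = 0.1)
  expect_equal(fisher_z(-r), -fisher_z(r))
  expect_error(fisher_z(1), "undefined")
  expect_error(fisher_z(-1.2), "undefined")
})

test_that("seed maps recover a planted seed-target correlation", {
  spec <- cohort_spec(n_rois = 3, n_volumes = 5000,
                      base_graph = list(neighbors_k = 2, rewire_prob = 0,
                                        graph_seed = 1),
                      effect_rois = integer(0), ar_coefficient = 0,
                      nuisance = list(global_amp = 0, drift_amp = 0,
                                      motion_amp = 0))
  cv <- diag(3)
  cv[1, 2] <- cv[2, 1] <- 0.6
  s <- simulate_subject(cv, spec, subject_seed = 21L)
  m <- seed_fc_map(s, seed_rois = 1)
  expect_length(m$z_values, 2)
  z12 <- m$z_values[m$roi_index == 2]
  expect_gt(z12, atanh(0.55))
  expect_lt(z12, atanh(0.65))
})

test_that("a seed perfectly correlated with a target is rejected", {
  x <- matrix(rnorm(60), 20, 3)
  x[, 2] <- x[, 1]
  expect_error(seed_fc_map(make_ts(x), seed_rois = 1), "undefined")
  # seed of two ROIs equal to the same signal, target equal to it too
  y <- cbind(x[, 1], x[, 1], x[, 1])
  expect_error(seed_fc_map(make_ts(y), seed_rois = 1:2), "undefined")
})

test_that("identical group maps give t = 0 and p = 1 everywhere", {
  set.seed(5)
  maps <- lapply(1:3, function(i) {
    list(roi_labels = paste0("r", 1:6), z_values = rnorm(6))
  })
  res <- group_fc_tests(maps, maps)
  expect_equal(res$t, rep(0, 6))
  expect_equal(res$p_uncorrected, rep(1, 6))
  expect_equal(res$q_fdr, rep(1, 6))
})

test_that("zero-variance ROIs give NaN statistics with a warning", {
  maps_a <- lapply(1:3, function(i) list(roi_labels = "r1", z_values = 0))
  maps_b <- lapply(1:3, function(i) list(roi_labels = "r1", z_values = 1))
  expect_warning(res <- group_fc_tests(maps_a, maps_b), "NaN")
  expect_true(is.nan(res$t[1]))
  expect_true(is.nan(res$p_uncorrected[1]))
})

test_that("group map tests are calibrated under the null", {
  set.seed(6)
  n_roi <- 1000
  maps_a <- lapply(1:17, function(i) {
    list(roi_labels = paste0("r", seq_len(n_roi)), z_values = rnorm(n_roi))
  })
  maps_b <- lapply(1:16, function(i) {
    list(roi_labels = paste0("r", seq_len(n_roi)), z_values = rnorm(n_roi))
  })
  res <- group_fc_tests(maps_a, maps_b)
  rate <- mean(res$p_uncorrected < 0.05)
  expect_gte(rate, 0.035)
  expect_lte(rate, 0.065)
})
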