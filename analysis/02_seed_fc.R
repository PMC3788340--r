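#!/usr/bin/env Rscript
# Step 2 — ROI-level seed-based functional connectivity.
#
# Preprocesses every subject (discard 4 volumes, detrend, 0.01-0.08 Hz
# ideal band-pass, regression of the stored nuisance regressors plus the
# global mean signal), then builds seed-FC maps for the subcortical seeds
# the group analysis focuses on (right amygdala; both nucleus accumbens
# ROIs) and compares Fisher-z maps between groups with two-sample t-tests
# and Benjamini-Hochberg FDR across ROIs.
#
# Output: results/seed_fc_<seed>.tsv, one row per non-seed ROI.

suppressPackageStartupMessages(library(netsweep))

parc <- load_parcellation()
coh <- read_cohort("scratch/cohort/manifest.tsv", tr_seconds = 2.34,
                   parcellation = parc)
pre <- lapply(coh$subjects, preprocess, cfg = preprocess_config())
is_a <- coh$manifest$group == "A"

seeds <- list(right_amygdala = 108L, nucleus_accumbens = c(109L, 110L))
dir.create("results", showWarnings = FALSE)
for (seed_name in names(seeds)) {
  maps <- lapply(pre, seed_fc_map, seed_rois = seeds[[seed_name]])
  res <- group_fc_tests(maps[is_a], maps[!is_a])
  out <- file.path("results", paste0("seed_fc_", seed_name, ".tsv"))
  write.table(format(res, digits = 4), out, sep = "\t", quote = FALSE,
              row.names = FALSE)
  n_sig <- sum(res$q_fdr < 0.05, na.rm = TRUE)
  top <- res[order(res$p_uncorrected), ][1, ]
  cat(sprintf("%s seed: %d/%d ROIs pass FDR 0.05; strongest ROI %s (t = %.2f, p = %.3g)\n",
              seed_name, n_sig, nrow(res), top$roi, top$t, top$p_uncorrected))
}
cat("written: results/seed_fc_*.tsv\n")
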