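# netsweep

Group-level graph-theoretical analysis of resting-state functional brain
networks, built for study designs that compare a trained expert cohort
with matched novices — for example long-term board-game (Baduk/Go)
experts versus players who merely know the rules.

The package takes per-subject ROI time series (plain TSV, one row per
volume, one column per region of the bundled 110-region
Harvard–Oxford-style parcellation), and carries them through the full
analysis chain:

1. preprocessing: discard initial volumes, detrend, ideal 0.01–0.08 Hz
   band-pass, nuisance + global-signal regression;
2. interregional Pearson correlation with Fisher z transform
   (z = artanh r);
3. binarization over a sparsity sweep S = 0.10, 0.11, …, 0.42, keeping
   at each S the K = round_half_up(S·N(N−1)/2) strongest edges;
4. graph metrics at every threshold — global: clustering coefficient
   C_P, harmonic characteristic path length L_P = 1/E_glob, global and
   local efficiency E_glob, E_loc; small-world parameters
   γ = C_P/C_P^rand, λ = L_P/L_P^rand, σ = γ/λ normalized against
   degree-matched Maslov–Sneppen random networks; nodal: degree D_nod,
   efficiency E_nod, betweenness B_nod (Brandes);
5. trapezoidal area-under-curve (AUC) summarization of every metric
   curve over the sweep;
6. inference: nonparametric permutation tests on group AUC differences,
   the "changed in at least one nodal metric (p < 0.05)" region rule,
   and Pearson correlations of regional AUC with training duration at
   the Bonferroni 0.05/110 level.

Because resting-state scans of this kind are generally not deposited,
the package includes a first-class synthetic cohort generator
(`cohort_spec()`, `generate_cohort()`): 17 + 16 subjects, 120 volumes at
TR = 2.34 s, BOLD-like band-limited signals whose covariance lives on a
Watts–Strogatz small-world backbone, shared nuisance confounds that the
preprocessing stage can regress exactly, expert training durations
~ N(12.47, 1.50²) years, and a tunable planted connectivity effect in
five subcortical ROIs. The methods vignette
(`vignettes/network-sweep-methods.Rmd`) documents every model choice and
what the generator does and does not emulate.

## Worked example

```r
library(netsweep)

spec <- cohort_spec(seed = 20260401)      # the default study design
res  <- run_pipeline(spec, n_null = 20, n_perm = 5000, seed = 20260401)
print(res)
```

```
<netsweep_result> 33 subjects, 33 sparsities
  min small-worldness sigma over subjects x sparsities: 1.152
  global metrics with permutation p < 0.05: e_loc, gamma, sigma
  regions flagged in at least one nodal metric: 14
```

Reading the output: every one of the 33 subjects' networks stays in the
small-world regime (σ > 1.1) across the whole sparsity range, so the
sweep is valid; the permutation tests detect group differences in the
normalized small-world parameters and local efficiency; and 14 regions
differ in at least one nodal centrality metric — including all five
ROIs (106–110, right hippocampus, both amygdalae, both accumbens areas)
in which this cohort's generating spec planted its connectivity effect,
the remainder being the union rule's expected false positives (its
per-region rate is ≈ 1 − 0.95³ ≈ 0.14; the per-metric p-values in
`res$flagged` allow stricter control).

`res$global_tests` holds the Table-style group comparison (mean AUC (SD)
per group and permutation p per global metric), `res$flagged` the
regions significant in at least one nodal metric with per-metric
p-values and directions, `res$training_cor` the training-duration
correlations. `write_results(res, dir)` writes all of it as TSV plus a
JSON run record from which the run can be reproduced bit-identically.

The `analysis/` directory holds the same workflow as numbered narrative
scripts (`01_simulate.R` … `04_report.R`), writing bulk data under
`scratch/` and summary tables under `results/`.

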