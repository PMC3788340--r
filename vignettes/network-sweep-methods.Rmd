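---
title: "Sparsity-sweep graph analysis of resting-state functional networks: models and design choices"
author: "netsweep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparsity-sweep graph analysis: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## What the package computes

netsweep implements a group-level graph-theoretical analysis of
resting-state functional connectivity of the kind used to compare an
expert cohort (here, long-term board-game experts) with matched novices.
The analysis chain is:

1. **ROI time series** — each subject is a T x N matrix (timepoints x
   regions of interest) with a repetition time TR. The bundled
   parcellation divides the brain, brainstem excluded, into 110
   Harvard-Oxford-style cortical and subcortical ROIs (55 per
   hemisphere), each ROI one network node.
2. **Preprocessing** (`preprocess()`) — discard the first 4 volumes,
   remove the per-ROI ordinary-least-squares linear trend, apply an ideal
   discrete-Fourier band-pass at 0.01-0.08 Hz, and regress out nuisance
   signals (supplied regressors plus the mean-across-ROIs global signal),
   in exactly that order.
3. **Connectivity** (`correlation_matrix()`) — Pearson correlations
   between all ROI pairs, Fisher-z transformed
   (z = artanh r), zero diagonal.
4. **Binarization** (`binarize_by_sparsity()`) — at each sparsity S in
   0.10, 0.11, ..., 0.42 keep the K = round_half_up(S N(N-1)/2) strongest
   edges, giving every subject a graph with identical node and edge
   counts at each threshold.
5. **Graph metrics** — global: clustering coefficient C_P,
   characteristic path length L_P, global efficiency E_glob, local
   efficiency E_loc; small-world normalization gamma = C_P/C_P^rand,
   lambda = L_P/L_P^rand, sigma = gamma/lambda against 100 degree-matched
   Maslov-Sneppen random networks; nodal: degree D_nod, efficiency E_nod,
   betweenness B_nod.
6. **AUC summarization** (`auc()`) — each metric's curve over the
   sparsity grid is integrated (trapezoid) into one scalar per subject,
   removing single-threshold arbitrariness.
7. **Inference** (`permutation_test()`, `flag_changed_regions()`,
   `correlate_training()`) — nonparametric permutation tests (5000
   permutations) on group differences in AUC; a region is reported as
   changed when at least one of its three nodal metrics has p < 0.05;
   Pearson correlation of regional AUC with training duration at the
   Bonferroni level 0.05/110.

The printed definitions are implemented literally:

- C_P(G) = (1/N) sum_i E_i / (D_i (D_i - 1)/2), where E_i is the edge
  count of the subgraph G_i induced by the neighbors of node i;
- E_glob(G) = (1/(N(N-1))) sum_{i != j} 1/L_ij with 1/Inf = 0;
- L_P(G) = 1 / E_glob(G) (the harmonic form — see below);
- E_loc(G) = (1/N) sum_i E_glob(G_i);
- E_nod(i) = (1/(N-1)) sum_{j != i} 1/L_ij;
- B_nod(i) = sum_{j != i != k} delta_jk(i)/delta_jk over unordered pairs,
  unnormalized (Freeman's definition), computed with Brandes'
  accumulation algorithm.

The compiled kernels (BFS shortest-path census, Brandes betweenness,
neighbor-subgraph efficiency, double-edge-swap rewiring) are verified in
the test suite against exhaustive brute-force enumeration (adjacency
matrix powers) on hundreds of small random graphs, and cross-checked
against an independent graph library.

## The synthetic cohort

No scan data ship with the package; `generate_cohort()` produces a
cohort that emulates the study design so the whole pipeline runs
end-to-end:

- 17 experts (group A) and 16 novices (group B); 120 volumes at
  TR = 2.34 s per subject (first 4 later discarded); 110 ROIs.
- Expert training durations drawn from Normal(12.47, 1.50^2) years,
  truncated at zero (truncation matters only in the far tail at these
  values).
- The interregional covariance is `edge_weight * A + diag_boost * I`
  (defaults 0.25 and 1.5) where A is a Watts-Strogatz graph: a ring
  lattice with `neighbors_k = 10` neighbors per node, each lattice edge
  rewired with probability 0.1. This backbone makes thresholded networks
  sit in the small-world regime (sigma > 1.1 across the whole grid for
  every subject, checked end-to-end in the acceptance battery).
- The backbone is drawn from its own fixed `graph_seed`, deliberately
  decoupled from the cohort seed: it plays the role of anatomy, so
  regenerating a cohort with a new seed resamples *subjects from the same
  population* rather than changing the population. This is what makes a
  power simulation over many cohorts meaningful.
- Subject signals are multivariate-normal draws smoothed by an AR(1)
  filter (`ar_coefficient = 0.3`, a realistic serial correlation for
  band-limited BOLD at this TR) plus shared nuisance components: a global
  random-walk signal, a linear drift, and six motion-like random-walk
  regressors with ROI-specific loadings (amplitudes 0.5/0.5/0.2). The
  true regressors are stored with each subject so preprocessing can
  regress exactly the confounds that were injected — the analog of
  regressing measured head-motion and global signals from real data.
- The group effect adds `effect_delta` to the covariance of base-graph
  edges whose endpoints both lie in `effect_rois` (default: the five
  contiguous subcortical ROIs 106-110, all ten mutual pairs being lattice
  edges), in group A only. Restricting the increment to existing edges
  keeps positive definiteness manageable (the constructor verifies the
  smallest eigenvalue and refuses otherwise) and plants a localized nodal
  difference without dictating its size at the metric level.

**Default effect size.** `effect_delta = 0.8` was chosen by the power
simulation that defines the planted-effect condition: across simulated
cohorts, the "at least one nodal metric" rule at alpha = 0.05 recovers at
least 4 of the 5 planted ROIs in >= 80% of cohorts (100-cohort check in
the acceptance battery). Two properties of the design make this the
operating point. First, the per-edge contrast saturates: novices already
carry the planted lattice edges at baseline strength, so the selection
probability gap between groups cannot exceed the backbone's own
detectability (baseline edge r = 0.167 against correlation noise of
SD ~ 0.16 at 116 band-limited volumes). Second, with global signal
regression a strongly coupled block *suppresses* its members' remaining
correlations, so at large delta the planted ROIs lose edges relative to
novices — the detected difference is two-sided, which the permutation
tests accommodate. Values much above 0.8 violate positive definiteness
on the default backbone; values below ~0.5 leave the rule underpowered
at n = 17/16.

What the generator does **not** emulate: voxel-level structure and
spatial smoothing, physiological (cardiac/respiratory) noise, real
head-motion artifacts, hemodynamic response shape, or inter-subject
anatomical variability. Passing tests therefore demonstrate the
correctness and calibration of the *pipeline*, not the realism of any
particular biological claim.

## Numerical and statistical choices

- **Edge ranking is signed.** Thresholding keeps the K largest signed z
  values; strong negative correlations are never selected. The
  literature is split on this; `rank_by = "absolute"` switches
  conventions.
- **K rounding is half-up.** At S = 0.10 with N = 110,
  0.10 x 5995 = 599.5 rounds to 600. This makes the convention
  observable and testable.
- **Ties at the sparsity cut** break lexicographically by (i, j), with a
  warning when the tie break is actually exercised (a degenerate,
  all-equal matrix still yields a deterministic graph).
- **L_P is harmonic.** The printed path-length equation is the
  reciprocal of the mean inverse distance, which forces
  L_P x E_glob = 1 and stays finite on disconnected graphs. The
  arithmetic mean over reachable pairs — the other common convention —
  is available via `global_metrics(..., path_length = "arithmetic")`,
  but the identity is the documented default.
- **Degenerate graph terms** are defined as zero: the C_P term of a node
  with degree < 2, and E_glob of a neighbor subgraph on < 2 nodes.
- **Null networks** use ceiling(10 |E|) attempted double-edge swaps
  (standard Maslov-Sneppen depth; configurable). Nulls are not forced to
  be connected — harmonic L_P handles disconnection — and a null with
  C_P = 0 or infinite L_P is excluded from the normalization means with
  a logged count. With zero swaps the normalization returns sigma = 1
  exactly, which the tests pin down.
- **Permutation tests** use the group-mean difference as statistic,
  two-sided. Monte-Carlo mode applies the add-one correction
  (p = (#{|null| >= |obs|} + 1)/(n_perm + 1), never 0); when the number
  of distinct splits is at most n_perm the test switches to exhaustive
  enumeration, where the observed split is one of the enumerated ones
  and the p-value is the exact exceedance fraction. Comparisons use a
  relative tolerance so p-values are invariant under affine rescaling of
  the inputs.
- **The nodal test battery** shares one permutation index set across all
  region x metric tests (a single matrix product), which is statistically
  standard and keeps the 330-test battery fast; the exported
  `permutation_test()` draws independently.
- **The union rule inflates alpha.** Flagging a region when *any* of
  three nodal metrics has p < 0.05 has a per-region false-positive rate
  near 1 - 0.95^3 ~ 0.14 under independence; the per-metric p-values are
  returned so users can apply stricter control. The acceptance battery
  accounts for this when counting false positives.
- **Seed-FC group maps** use the pooled-variance Student t (the simplest
  reading of "two-sample t-tests") with Benjamini-Hochberg FDR across
  ROIs; ROI-level FDR replaces voxelwise cluster corrections, which need
  voxel grids. A zero-variance ROI yields NaN with a warning rather than
  aborting a cohort run.

## Reproducibility

One master seed fixes every random draw: per-subject simulation seeds,
per-subject-per-threshold null-network streams, and permutation draws
are all derived deterministically (a hash chain kept below 2^31), so
results are independent of execution order and two runs of
`run_pipeline()` from the same seed are bit-identical — including the
TSV/JSON files written by `write_results()`. The run record JSON stores
the full spec, grid, seeds and package versions needed to re-execute a
run.

## Problem sizes used in the test suite

The suite exercises the full study geometry where the claim depends on
it (33 subjects x 110 ROIs x 33 sparsities for the small-world screening
and the 100-cohort power simulation, with 20 nulls per subject-threshold
and 1000 permutations there) and scales everything else down to the
smallest size that still identifies the property: oracle equivalence on
graphs of up to 12 nodes where exhaustive enumeration is feasible,
calibration checks at 1000 simulated datasets, determinism on a
30-ROI/8-subject configuration. Tiny-backbone test cohorts use
`effect_delta = 0.3` because the 0.8 default is calibrated for — and
only positive-definite on — the full 110-ROI, k = 10 backbone.

## Known limitations

- The ROI-level global signal (mean across ROI columns) is an analog,
  not a reimplementation, of whole-brain global signal regression on
  voxel data; likewise ROI-level FDR stands in for voxelwise cluster
  corrections.
- The region-flagging rule is implemented verbatim ("significant in at
  least one nodal metric at p < 0.05") even though it inflates
  per-region type-I error; no additional correction step is applied
  because none is defined for it.
- Betweenness is unnormalized; its magnitude scales with network size
  and should not be compared across parcellations of different N.
- AUC is undefined (flagged NA) if any curve value is non-finite. The
  harmonic L_P is infinite only for a graph with no reachable pair at
  all (E_glob = 0), which cannot occur on the default grid where every
  threshold keeps at least 600 edges.
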