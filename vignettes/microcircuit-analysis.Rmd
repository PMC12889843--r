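---
title: "From calcium traces to predictive microcircuit topology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From calcium traces to predictive microcircuit topology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(miniconn)
```

## What this package computes

`miniconn` implements an analysis chain for single-neuron calcium imaging
recorded across behavioral stages, of the kind produced by head-mounted
miniscopes during three-stage social behavior tests (habituation **H**,
sociability **SB**, social novelty **SN**, each typically 10 min at 10
frames/s):

1. **Activity** — per-neuron dF/F traces are max-normalized and summarized
   as *AUC per 100 s* (100 × the time mean of the normalized trace) and a
   rising-edge event rate.
2. **Functional graphs** — per stage, pairwise Pearson correlations of the
   dF/F traces are thresholded into a binary, undirected adjacency matrix
   over the session's fixed neuron set.
3. **Topology** — characteristic path length `L_g`, mean local clustering
   `C_l`, global clustering (transitivity) `C_g`, degree-tail hub
   identification, and the Laplacian spectral distance
   `s = sqrt(sum_i (lambda_i - omega_i)^2 / N)` between the sorted spectra
   of two stage graphs on the same neurons — a global measure of
   cross-stage network reconfiguration.
4. **Prediction** — session-level features (stage AUCs, stage-pair spectral
   distances, stage-wise `L_g`, `C_l`, `C_g`) feed three random-forest
   frameworks under genotype-balanced nested leave-pairs-out
   cross-validation with recursive feature elimination (RFE): Model 1
   predicts genotype, Model 2 predicts a high/low social-motivation label,
   Model 3 predicts motivation with genotype as an extra predictor.
   In-silico ablations retrain the identical pipeline after deleting the
   activity (AUC) features, the spectral-distance features, or both.

Because real cohorts of this kind are rarely shareable, the package ships a
synthetic-cohort generator whose ground truth is known, making every stage
of the chain testable end to end.

## Model assumptions

* Functional connectivity is *statistical*: an edge means correlated dF/F
  within a stage, not an anatomical synapse. The binarization threshold is
  a free analysis parameter (default 0.3, strict `>`), and
  `threshold_sweep()` exists precisely because conclusions should be
  checked across it. Negative correlations never create edges.
* The spectral distance requires the two graphs to share one node set;
  the pipeline therefore builds all three stage graphs of a session over
  the identical neuron panel, and the generator honors the same
  constraint.
* Mice, not sessions, are the experimental unit. Every cross-validation
  split moves *all* sessions of a held-out mouse together, and fold
  enumeration is genotype-balanced (two mice per genotype held out in the
  outer loop, one per genotype in the inner loop). A runtime guard asserts
  train/test mouse disjointness in every fold.

## Parameters that matter

| parameter | units | default | why |
|---|---|---|---|
| correlation threshold | r | 0.3 | unstated in the field's typical reports; made explicit and sweepable |
| event detection `k_sd` | SD of first differences | 5 | conventional conservative transient criterion |
| winsorization width | MAD | 3 | robust univariate clipping; MAD deliberately *unscaled* (no 1.4826 factor), the factor is exposed as `mad_scale` |
| Mahalanobis cutoff | chi-square prob. | 0.975 | conventional multivariate outlier screen at `qchisq(0.975, p)` |
| transform offset `eps` | — | 1e-6 | spectral distances and `C_g` can be exactly 0 on sparse graphs; log/inverse transforms need a guard |
| trees per forest | count | 500 | common default; exposed in `ml_control()` |
| mtry grid | count | `1..ceiling(sqrt(p))` | standard random-forest tuning range |
| RFE subset sizes | count | `1..p` | exhaustive; coarser grids via `ml_control()` |

## The synthetic cohort: what it emulates, and what it does not

`cohort_config()` defaults emulate a two-genotype study (11 + 9 mice,
five sessions, three 10-min stages at 10 Hz, 60–90 neurons per mouse).
Genotype effects are injected through four dials:

* **activity**: per-neuron Poisson event rates 0.5 Hz (WT) vs 0.3 Hz (KO),
  within the range typical of prefrontal GCaMP recordings;
* **topology**: Watts–Strogatz stage networks of mean degree 4 with
  rewiring probability 0.10 (WT) vs 0.05 (KO) — the affected genotype is
  more lattice-like, hence less integrated (longer `L_g`);
* **reconfiguration**: between the H baseline and each social stage,
  15% (WT) vs 6% (KO) of edges are rewired, so WT networks show larger
  cross-stage spectral distances;
* **behavior**: preference percentages centered at 65 (WT) vs 45 (KO)
  with SD 8, about a 2.5-SD separation.

Traces are built exactly as the correlation analysis assumes: each source
event (exponential amplitude, mean 0.08 dF/F) is copied onto each graph
neighbor with probability `coupling = 0.9` in the same frame, trains are
convolved with a 0.3-s single-exponential kernel, Gaussian noise
(SD 0.05) is added and traces are clipped at zero.

Three generator choices deserve explanation:

* **Exponential event amplitudes.** With constant amplitudes the trace
  maximum grows with the firing rate (Poisson pileup), which makes the
  *max-normalized* AUC anti-monotone in the rate — the opposite of the
  effect the activity dial is supposed to inject. Amplitude variability
  puts the maximum in the amplitude tail, which grows only
  logarithmically with event count, so AUC increases with rate as
  intended. Copies inherit the source amplitude, leaving the pairwise
  correlation structure unchanged.
* **A 0.3-s kernel.** A slower kernel (0.5 s) blurs enough temporal
  structure at 10 Hz that correlations of neurons two steps apart in the
  graph approach the direct-edge correlations and edge recovery at the
  default threshold degrades; 0.3 s is still within the GCaMP6f decay
  range and keeps the two populations separable.
* **Neighborhood-biased stage rewiring.** New cross-stage edges are drawn
  from node pairs that already share a neighbor (`local = TRUE`).
  Uniformly placed edges have no common neighbor, and the shared-event
  correlation they induce is systematically weaker than that of clustered
  edges — they would be invisible to any threshold that still rejects
  spurious second-neighbor correlations. Biologically, circuit remodeling
  is neighborhood-biased; statistically, this keeps ground-truth recovery
  a fair target. The uniform variant remains available.

What the generator does **not** emulate: pixel-level imaging artifacts,
motion, cell-extraction errors, bursting/refractory dynamics, rate
nonstationarity within a stage, inhibitory (negative) coupling, and any
clustering-coefficient *deficit* in the affected genotype — with equal
mean degree, the less-rewired KO lattice is slightly *more* clustered, so
passing tests demonstrate correct mechanics and recoverable injected
effects, not that every real-data group difference is reproduced in
direction.

## Numerical and procedural choices

* **AUC formula**: defined as 100 × time-mean of the max-normalized trace
  — frame-rate invariant and bounded in [0, 100]; a literal frame-sum
  divided by seconds would depend on the frame rate.
* **Normalization scope**: per neuron over the whole session, so stage
  AUCs are comparable within a neuron.
* **Event detector**: a rising-edge threshold at 5 SD of the first
  differences replaces model-based deconvolution; event rate is reported
  but is not a model feature.
* **Constant traces**: Pearson correlation is undefined; defined here as 0
  (degenerate neurons never create edges), with a warning.
* **Disconnected graphs**: `L_g` averages over *reachable* ordered pairs
  and reports their count; a largest-component variant is available by
  flag. A graph with no edges has `L_g = NA` with a warning.
* **Laplacian spectra**: computed by a dense symmetric eigensolver;
  floating-point negatives above −1e-10 are clipped to 0. Spectra are
  sorted ascending before pairing; the zero mode is included by default,
  with `exclude_zero_mode = TRUE` reproducing the illustration variant
  (drop the smallest eigenvalue, divide by N − 1).
* **Hub rule**: `p_i` is the fraction of nodes (self included) with degree
  at least `d_i`; hubs are `p_i <= 0.05`. Ties make the rule conservative:
  never more than `alpha * N` hubs.
* **Motivation threshold**: candidates are midpoints between adjacent
  sorted unique composite scores; the minimizer of the distance to the
  ROC top-left corner wins, ties to the smaller threshold; the positive
  class is the lower-scoring (affected) genotype; a score exactly at the
  threshold is "low". The threshold is set once on the full table and
  never re-tuned inside cross-validation.
* **Preprocessing order**: transforms, then per-column 3-MAD
  winsorization, then the Mahalanobis screen (flagged rows are *removed*
  by default; a flag-only mode exists), then restriction to the fixed
  11-feature candidate subset (`AUC_H, AUC_SB, AUC_SN, s_H_SB, s_H_SN,
  Lg_SB, Cl_SB, Cl_SN, Cg_H, Cg_SB, Cg_SN`). Preprocessing runs once on
  the full table — a deliberate, logged leakage trade-off that keeps the
  feature space identical across folds; data-driven pruning
  (`prune_correlated()`, cutoff 0.8, drop the column with the larger mean
  absolute correlation, ties to the earlier column) is available instead.
* **RFE**: features are ranked by permutation importance averaged over
  inner-training fits; subset sizes are scored by mean inner-validation
  ROC-AUC (rank-based, tested against pROC); ties prefer fewer features,
  then smaller mtry. The tuned forest is refit on the full outer-training
  set; the outer test set is scored once.
* **Report aggregation**: the headline ROC-AUC pools scores across outer
  folds (threshold-free); a vertically averaged ROC curve on a fixed FPR
  grid is also reported, as is the mean of per-fold AUCs. Confusion counts
  at the 0.5 probability threshold (ties to the negative class) are summed
  over folds and row-normalized per true class; sensitivity, specificity,
  PPV, NPV and accuracy derive from that normalized matrix. Selection
  frequency divides by the number of outer folds actually executed.

## Problem sizes used by the test suite

The packaged tests exercise the full pipeline at desk scale: cohorts of
5 + 5 (or 3 + 3) mice, 60–600 s stages, 30–50 neurons, forests of 40–100
trees, and outer loops subsampled to 15–30 of the enumerated folds (the
subsample is seeded and uniform). Edge-recovery checks use full-length
600-s stages, where correlation estimates are tight. The full-scale
defaults (11 + 9 mice, 1,980 exhaustively enumerated outer folds, 500
trees) are the package defaults and run unchanged — they are simply larger
than a test suite needs.

## Known limitations

* Binary graphs discard correlation magnitude; no weighted, partial
  correlation, or shuffle-null edge tests are provided.
* The spectral distance is a pseudometric on sorted spectra: cospectral
  graphs are indistinguishable.
* With very few mice per genotype the inner leave-one-pair-out loop has
  few validation pairs, and RFE subset choice becomes noisy.
* Preprocessing-before-CV slightly optimistic-biases the nested-CV
  estimates; the trade-off is logged rather than hidden.
* The motivation label derives from genotype separation in behavior, so
  Models 2 and 3 inherit any genotype imbalance in the behavioral dial.
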