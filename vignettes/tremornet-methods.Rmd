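---
title: "Methods: voxel-wise centrality and weighted network efficiency for two-group resting-state fMRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: voxel-wise centrality and weighted network efficiency}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tremornet)
```

# Overview

`tremornet` implements a resting-state fMRI "discoordination" analysis for
two-group (patient versus control) designs, of the kind used to
characterize network-level abnormalities in tremor-dominant Parkinson's
disease. The pipeline runs in five stages:

1. **Temporal preprocessing** of each 4D BOLD run: leading-volume removal,
   per-voxel linear detrending, band-pass filtering, and nuisance
   regression (Friston-24 motion expansion plus mean white-matter and CSF
   series), together with head-motion summary scalars.
2. **Voxel-wise weighted degree centrality (WDC)**: for every grey-matter
   voxel $i$, $S_i = \sum_{j \ne i} r_{ij}\,[r_{ij} \ge r_0]$, the sum of
   suprathreshold positive Pearson correlations with all other voxels.
3. **Seed-based functional connectivity**: 6-mm sphere ROIs at the peak
   voxels of group-difference clusters, mean-series extraction, voxel-wise
   correlation and Fisher $z = \operatorname{artanh}(r)$ maps.
4. **Weighted network efficiency** of the ROI network over a sparsity
   sweep, with degree-preserving null normalization and small-world
   assessment.
5. **Group statistics**: covariate-adjusted GLM t-maps with Monte-Carlo
   cluster-extent correction, Freedman-Lane permutation tests with
   Benjamini-Hochberg correction across sparsities, partial Spearman
   brain-behavior correlation, and ROC discrimination.

Because no patient data are distributed with the package, every stage is
exercised against a **synthetic cohort generator** whose ground truth
(planted covariance, hub voxels, group effect, score coupling) is known
exactly, so recovery can be verified rather than assumed.

# The synthetic cohort model

Each subject's voxel series is region-structured multivariate noise. The
grid is partitioned into `n_regions` contiguous, equally sized regions.
Per subject, region latent signals are drawn from
$\mathcal{N}(0, \Sigma_g)$ over time, where $\Sigma_A$ is the configured
`base_cov` and $\Sigma_B = \Sigma_A + s_i\,\Delta$ adds the planted group
effect `effect_delta`, scaled by a positive per-subject severity
$s_i \sim \exp(\mathcal{N}(0, 0.25))$. The latents are band-pass shaped
(same ideal filter as preprocessing) and rescaled to unit variance *before*
white voxel noise is added, which keeps realized inter-regional
correlations close to their nominal values; the package verifies this
calibration directly (a nominal $r = 0.6$ pair is recovered within
$\pm 0.05$ when pooled over 200 subjects).

Default conditions emulate a typical tremor-PD resting-state study: 20
controls versus 16 patients, 180 volumes at TR = 2 s, pass band
0.01–0.1 Hz, 3-mm isotropic voxels. Values the emulated regime does not
pin down were chosen once, on realism grounds:

* **`base_cov`** defaults to a *modular* correlation matrix
  (`modular_base_cov`: two modules, $r = 0.45$ within, $0.15$ between).
  Resting-state ROI networks are modular, and modularity is what makes the
  thresholded graphs small-world (clustered yet short-pathed); an
  equicorrelated alternative would produce Erdős–Rényi-like graphs with
  normalized local efficiency $\approx 1$, a regime the method is not
  designed for.
* **`effect_delta`** defaults to a uniform $+0.15$ on every off-diagonal
  pair — a diffuse, positive connectivity increase in the patient group,
  matching the direction of the clinical phenomenon (widespread
  hyperconnectivity) at a moderate-to-large effect size.
* **Hub voxels** (default: the grid-centre voxel) carry the average of all
  region latents with reduced noise, so they have the largest expected
  correlation sum and give the centrality stage a recoverable target.
* **Clinical scores** are `center + slope * latent + noise`, clipped to
  plausible clinical ranges (tremor 1–4, H–Y 1–3, UPDRS 4–49, MMSE 29–30,
  duration 0.4–6 years); the latent is the same severity $s_i$ that scales
  the connectivity effect, so brain-behavior coupling is genuine. Controls
  receive missing codes for disease scores, as in clinical tables.
* **Motion traces** are reflecting random walks (translations in mm,
  rotations in radians, SPM `rp_*.txt` column order) bounded at 2.7 mm /
  2.7°, safely inside the conventional 3 mm / 3° exclusion rule.

All randomness derives from one integer seed through a fixed splitting
scheme (`subject`, `clinical`, `motion`, and `null-model` streams), so a
cohort is a bit-reproducible function of its configuration.

**What the generator does not emulate:** scanner artefacts, physiological
noise regressors, spatial autocorrelation beyond region structure, real
anatomy (no WM/CSF compartments; nuisance masks are optional inputs), and
any specific regional geometry of the clinical condition. Passing tests
therefore demonstrate correctness of the estimators and calibration of the
inference under the stated generative model — not robustness to the full
noise structure of real scanner data.

# Preprocessing choices

* The band-pass is an **ideal (rectangular) frequency-domain filter**:
  Fourier coefficients outside the band are zeroed. This matches the
  convention of the resting-state toolbox family, is exactly idempotent,
  and has no transition band to reason about. A Butterworth mode
  (order 2, forward-backward via the `signal` package) is available for
  users who prefer smooth roll-off. Detrending happens before filtering;
  note that re-detrending a band-limited signal is *not* a no-op on finite
  windows, so idempotence holds for the filter proper.
* The fixed temporal order is drop-volumes (default 5) → detrend →
  band-pass → nuisance regression.
* Frame-wise displacement is the sum of absolute backward differences of
  the six parameters with rotations converted to arc length on a **50-mm
  sphere** — the common convention; the source literature names mean FD
  without a formula, so this is a documented package decision.
* No spatial smoothing is offered anywhere before centrality: smoothing
  induces spurious local correlations that inflate voxel-wise degree.

# Centrality and seed connectivity

The correlation floor is significance-based: the smallest $r$ whose
two-sided p-value (t-transform, $df = T - 2$) reaches
$\alpha / n_\text{tests}$. The Bonferroni denominator defaults to
**$N - 1$ tests per seed voxel** (the per-row framing of the degree sum);
a whole-brain pairwise denominator $N(N-1)/2$ is available via
`n_tests_mode = "pairwise"`. Negative correlations are excluded throughout
(ambiguous interpretation, poor test-retest reliability), so $S_i \ge 0$.
The correlation matrix is processed in row blocks (default 512) to bound
memory; blockwise results equal the naive all-pairs computation to
$10^{-10}$, which the tests assert on sub-$10^3$-voxel grids.

Sphere ROIs take all in-mask voxels whose *centres* lie within the radius
of the centre coordinate (mm, through the image affine); on a 3-mm grid a
6-mm sphere holds 33 voxels. Overlapping ROIs are resolved greedily:
walking the list in order, an ROI is kept only if it shares no voxel with
any ROI already kept — a deterministic "drop the later-listed" rule, with
dropped indices logged. Correlations are clipped to $\pm(1 - 10^{-7})$
before the Fisher transform so z-maps are finite; constant voxels get
$z = 0$ and are flagged.

# Network efficiency

Edges are the largest positive correlations, kept to
$\mathrm{round}(s\,N(N-1)/2)$ edges at sparsity $s$, ranked by value with
lexicographic node-pair tie-breaking — which makes edge sets *nested*
across the sweep and global efficiency monotone in $s$. Edge length is the
reciprocal of the edge weight. Global efficiency is the mean inverse
shortest-path length over ordered pairs; disconnected pairs contribute 0.
Local efficiency is the mean, over nodes, of the global efficiency of the
neighbour-induced subgraph with original weights; nodes with fewer than two
neighbours contribute 0. Shortest paths use a vectorized Floyd–Warshall —
at ROI-network sizes ($\le$ a few dozen nodes) this is faster than graph
library round-trips, and it is verified in the tests against both
exhaustive path enumeration (all graphs $\le 8$ nodes) and an independent
Dijkstra implementation.

Null models are Maslov–Sneppen double-edge swaps on the binary topology
(default 100 surrogates, 10 accepted swaps per edge, retry budget
100 swaps-per-target with a warning on exhaustion). Each edge carries its
weight through the swap, preserving node count, edge count, the full
binary degree sequence, and the weight multiset exactly. The sweep default
is $0.08 \le s \le 0.6$ in steps of 0.02 (27 points); curves are
summarized by the trapezoidal AUC, and the small-world flag requires
normalized local efficiency $> 1$ with normalized global efficiency within
0.2 of 1 over at least half the grid. Graphs with fewer than two edges
(possible at the sparsest grid points on small networks) are treated as
their own null. Whether efficiency weights should be raw correlations or
Fisher-z values is genuinely open; raw correlations are used, consistent
with defining edge length as the reciprocal of the correlation
coefficient.

# Group statistics

* The voxel-wise GLM regresses each subject's map value on a group
  indicator plus covariates (gender, age, and the three motion summaries
  for functional comparisons); with no covariates the group t equals the
  classical pooled two-sample t exactly. Voxel-wise grey-matter-volume
  covariates can enter the model voxel by voxel to test the structural
  contribution to functional differences; the tests verify that a
  covariate which fully explains the group difference drives the group t
  toward zero.
* Cluster-extent correction thresholds at an uncorrected height
  (default $p < 0.01$ two-sided — the source literature leaves the height
  unstated, so it is configurable and always logged), labels 26-connected
  components, and removes clusters smaller than the $1 - \alpha$ quantile
  of the maximum null cluster size over simulated Gaussian fields
  (default 1000) whose per-axis smoothness can be matched to the residual
  maps via a gradient-variance FWHM estimate.
* Permutation tests use the Freedman–Lane scheme (the covariate-aware
  scheme with the best small-sample properties): residualize the metric on
  the covariates, permute group labels over residuals, statistic =
  difference of adjusted group means, add-one p-value. Default 10,000
  permutations; per-sparsity p-values are corrected by Benjamini–Hochberg
  across the 27 grid points. Calibration (type-I error at the study's
  16-vs-20 group sizes inside the binomial 95% interval; empirical FDR at
  or below q) is asserted in the test suite by simulation.
* Partial Spearman correlation rank-transforms both variables,
  residualizes the ranks on the covariates, and reports the Pearson
  correlation of residuals with a t-approximation p-value on
  $n - 2 - k$ degrees of freedom.
* ROC analysis sweeps all distinct score thresholds; the AUC uses the
  Mann–Whitney identity (ties count one half) and the reported operating
  point maximizes Youden's $J$. Sensitivity and specificity are reported
  rounded to one decimal percent.

# Problem sizes and runtime

The package's own verification runs at deliberately reduced scale so the
full suite completes in minutes on one CPU: the end-to-end study uses the
emulated cohort (36 subjects, $12^3$ grid, 180 volumes, 27 sparsities, 100
nulls, 10,000 permutations; about a minute), cohort-recovery checks use 100
cohorts on $6^3$ grids, calibration uses 1000 null simulations with 499
permutations each, and oracle-equivalence checks use 200 random graphs of
at most 8 nodes plus sub-$10^3$-voxel centrality grids. These sizes are
stated in the tests themselves; nothing in the methods depends on them.

# Known limitations

* Spatial preprocessing (slice timing, realignment, normalization,
  segmentation) is out of scope; inputs are assumed aligned to a common
  grid. Grey-matter-volume maps, when used as covariates, are accepted as
  inputs rather than computed.
* The Monte-Carlo cluster simulation uses a stationary Gaussian smoothness
  model estimated from residual maps; real fMRI residual fields are
  non-stationary and heavier-tailed, so corrected cluster inference on
  real data should be interpreted with the usual caution.
* Efficiency metrics are defined for non-negative weights only; negative
  correlations are excluded by construction rather than modelled.
* The generator's per-subject severity couples all clinical scores to a
  single latent; real symptom dimensions are not unidimensional.
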