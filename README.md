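# tremornet

Voxel-wise centrality and weighted network efficiency analysis of
resting-state fMRI cohorts.

## The problem

Tremor-dominant Parkinson's disease is poorly explained by the classical
basal-ganglia dopamine account, and resting-state fMRI studies instead
point to a *distributed* discoordination of spontaneous activity: widely
increased functional connectivity, altered hub structure, and more
efficient (more randomly wired) network topology in patients. Testing
such claims requires a chain of estimators — voxel-level graph centrality,
seed connectivity, thresholded weighted-network metrics, permutation
inference — each with many silent conventions. `tremornet` implements
that chain as a tested, reusable R pipeline for two-group designs, and
pairs it with a synthetic BOLD cohort generator with known ground truth so
every stage can be validated by recovery rather than by eye.

The package is for neuroimaging methodologists and statisticians who want
a transparent, scriptable reference implementation of this analysis family
with its conventions stated and its calibration demonstrated.

## What it computes

* **Weighted degree centrality** per grey-matter voxel
  (*S<sub>i</sub>* = Σ<sub>j≠i</sub> r<sub>ij</sub> over positive
  correlations surviving a Bonferroni-corrected significance floor).
* **Seed-based connectivity**: 6-mm sphere ROIs at group-difference
  cluster peaks, Fisher *z* = artanh(*r*) maps.
* **Weighted network efficiency** over a sparsity sweep
  (0.08–0.6, step 0.02): global efficiency
  *E*<sub>glob</sub> = (1/N(N−1)) Σ<sub>i≠j</sub> 1/d<sub>ij</sub> with
  edge length 1/weight, local efficiency as the mean neighbour-subgraph
  global efficiency, trapezoidal AUC summaries, and normalization by
  degree-preserving Maslov–Sneppen surrogates for small-world assessment.
* **Group inference**: covariate-adjusted GLM t-maps with Monte-Carlo
  cluster-extent correction, Freedman–Lane permutation tests with BH-FDR
  across sparsities, partial Spearman brain–behavior correlation, and ROC
  discrimination (Mann–Whitney AUC, Youden operating point).
* **Synthetic cohorts**: band-limited, region-structured BOLD with a
  modular covariance, planted hub voxels, a planted patient-group
  connectivity increase, motion traces, and clinical scores coupled to the
  planted severity.

See `vignettes/tremornet-methods.Rmd` for the model, conventions, and
design decisions.

## Worked example

Simulate the default study (20 controls vs 16 patients, 12³ grid, 180
volumes at TR = 2 s) and run the whole pipeline:

```r
library(tremornet)
cfg <- synthetic_config(seed = 7)
res <- run_pipeline(cfg, out_dir = "study_out")
print(res)
#> <tremornet_result>
#>   1728 GM voxels, WDC r floor 0.3105, 1 surviving cluster(s), 8 ROIs
#>   efficiency AUC: E_glob p = 9.999e-05, E_loc p = 0.0002 (14 / 10 sparsities FDR-significant)
#>   small-world: controls TRUE, patients TRUE
#>   ROC (region01--region04): AUC = 0.919, sensitivity 87.5%, specificity 80.0%
```

Reading the output: the centrality stage kept correlations above
*r* = 0.31 (the Bonferroni floor at α = 0.05 over 1727 tests per voxel,
df = 173); one cluster of abnormal centrality survived extent correction
and seeded the ROI network (topped up to 8 nodes with region seeds). Both
groups' mean networks are small-world, and the planted patient-group
connectivity increase is detected: the permutation p-values for the
efficiency-AUC group differences are ≈ 10⁻⁴ (E_glob) and 2 × 10⁻⁴
(E_loc), significant at 14 and 10 of the 27 sparsities after FDR. The most
discriminative connection separates patients from controls with AUC 0.919.

`study_out/` then contains the t-map and corrected-cluster NIfTIs, seed
table, group correlation matrices, weighted edge lists, efficiency curves
with per-sparsity p-values, per-subject AUCs, the ROC table, and a
`summary.json` run log with every threshold and seed.

The same run is available from the shell:

```sh
Rscript inst/cli/tremornet.R pipeline --seed 7 --out study_out
```

(subcommands: `simulate`, `pipeline`, `wdc`, `neteff`, `roc`).

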