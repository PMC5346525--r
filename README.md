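# brainnetdyn

Multimodal brain-network topology and dynamics for two-group clinical
cohorts.

Studies of cancer-related cognitive impairment increasingly ask whether
brain organization is already altered in newly diagnosed, *pretreatment*
patients. `brainnetdyn` implements the full analysis pipeline such a
study needs, in R, end to end:

- **Functional connectomes** from region-of-interest time series:
  pairwise Pearson correlation over 90 atlas regions, Fisher r-to-z
  normalized, `z = atanh(r)`.
- **Structural gray-matter similarity networks** per subject: nodes are
  non-overlapping 3×3×3-voxel cubes of the gray-matter density volume,
  edges are Pearson correlations between the cubes' 27 paired values
  (optionally maximized over the 48 right-angle cube rotations).
- **Minimum connection density thresholding**: both modalities are
  binarized at the smallest cohort-common edge density at which every
  subject's network is a single connected component.
- **Clustering-coefficient topology**: local clustering
  `C_i = 2T_i / (k_i (k_i − 1))` and its mean (global clustering), with
  structural cube-level clustering aggregated to the 90 atlas labels.
- **Functional dynamics**: per-region rescaled-range Hurst exponents,
  `Ĥ = 0.5 + slope[log2 (R/S)_d − log2 E(R/S)_d ~ log2 d]`, with the
  Anis–Lloyd–Peters small-sample correction and a divisor-maximizing
  window base (180 for 216-volume series).
- **Group statistics**: covariate-adjusted GLM comparisons with
  Benjamini–Hochberg FDR, Wilcoxon rank tests for non-normal outcomes,
  correlation inference, Fisher r-to-z comparison of independent
  correlations `z = (atanh r1 − atanh r2) / sqrt(1/(n1−3) + 1/(n2−3))`,
  a two-metric PCA of structural vs functional clustering, and a
  log-Mahalanobis cognitive composite measuring each patient's deviance
  from the control profile.

No clinical data are bundled. A **synthetic-cohort generator** with
known ground truth (exact fractional Gaussian noise by circulant
embedding, block-correlated region signals, smooth gray-matter fields, a
patient-only structure–function coupling injection, and group-structured
cognitive scores) makes every stage testable, including parameter
recovery and detection power.

## Worked example

The `analysis/` scripts run the whole workflow on the default synthetic
cohort (30 patients / 30 controls) and narrate what they find:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_build_networks.R
Rscript analysis/03_metrics_and_hurst.R
Rscript analysis/04_group_statistics.R
Rscript analysis/05_calibration.R
```

Output of the run recorded while writing this README:

```
Functional connectomes: 90 nodes, minimum connection density 0.2072
Structural connectomes: 268 cube nodes on average (SD 6.2), minimum connection density 0.2627
Window base for Hurst estimation: 180
Global Hurst          : 0.256 (pat) vs 0.295 (ctrl)  [true 0.19 vs 0.22]
SC-FC coupling: r = -0.68 (patients, p = 0.000) vs -0.14 (controls, p = 0.469)
Fisher comparison of the two correlations: z = -2.52, p = 0.0117
Global Hurst rank test: U = 639, p = 0.005
PCA component 1 explains 70% of SC/FC clustering variance
Hurst null (T = 216): mean 0.485 (target 0.5)
Hurst recovery (H = 0.8, T = 4096): mean 0.802
```

Reading this: the injected patient-only negative correlation between
structural and functional clustering is recovered (r = −0.68 vs −0.14,
Fisher comparison p ≈ .01); the patients' lower true Hurst exponent
(0.19 vs 0.22) surfaces as a significant rank test despite the
estimator's conservative shrinkage toward 0.5; and the estimator is
calibrated at the white-noise null. Stage outputs land under
`results/` as CSV/TSV/JSON (cohort table with `fc_global_clust`,
`sc_global_clust`, `sc_n_nodes`, `global_h`; per-region nodal tables;
one CSV per statistical layer).

Programmatic use mirrors the scripts:

```r
library(brainnetdyn)
cfg <- simulation_config(seed = 1)        # defaults define the cohort
res <- run_pipeline(cfg, out_dir = "results/run1")
res$stats$coupling                        # SC/FC/Hurst coupling + Fisher tests
res$stats$global_metrics                  # GLM F / Wilcoxon U per metric
```

## Repository layout

```
R/                  package code: synthetic cohort, functional/structural
                    networks, graph metrics, Hurst dynamics, statistics,
                    pipeline orchestration, IO
analysis/           numbered workflow scripts (simulate → networks →
                    metrics → statistics → calibration)
scripts/acceptance.R  headline-number recomputation (JSON out)
tests/testthat/     unit, property and acceptance suites with
                    independent brute-force oracles
vignettes/          methods vignette: models, assumptions, parameter
                    choices, limitations
```
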