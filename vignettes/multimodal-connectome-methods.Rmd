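---
title: "Multimodal brain-network topology and dynamics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal brain-network topology and dynamics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brainnetdyn)
```

## What the package computes

`brainnetdyn` implements an analysis pipeline for two-group
(patient/control) multimodal brain-network studies, of the kind used to
ask whether newly diagnosed, not-yet-treated breast-cancer patients
already show altered brain organization. Three layers of measurement feed
one statistics layer:

1. **Functional connectomes.** Pairwise Pearson correlations between the
   resting-state time courses of 90 atlas regions, variance-stabilized
   with the Fisher r-to-z transform (`correlation_matrix()`).
2. **Structural gray-matter similarity networks.** A single-subject
   network whose nodes are non-overlapping 3x3x3-voxel cubes of the
   gray-matter density volume and whose edge weights are Pearson
   correlations between the cubes' 27 paired values
   (`extract_cubes()`, `build_similarity_matrix()`).
3. **Functional dynamics.** A per-region rescaled-range Hurst exponent
   with small-sample bias correction (`hurst_exponent()`), summarizing
   the "long memory" of each region's signal.

Both connectome modalities are thresholded at the *cohort-common minimum
connection density* — the smallest edge density at which every subject's
network forms a single connected component (`find_min_density()`) — and
summarized by binary local/global clustering coefficients
(`clustering_coefficients()`), the standard measure of network
segregation. The statistics layer (`run_statistical_battery()`) then
reproduces the full inference chain: covariate-adjusted GLM group
comparisons with Benjamini-Hochberg FDR, Wilcoxon rank tests for the
non-normal Hurst outcome, within-group correlations among the three
global metrics with between-group Fisher r-to-z comparisons, a
two-metric PCA of structural and functional clustering, and a
log-Mahalanobis cognitive composite measuring each patient's deviance
from the control profile.

Because no clinical data ship with the package, a synthetic-cohort
generator (`simulation_config()`, `simulate_cohort()`) produces inputs
with known ground truth so every stage — and the pipeline end to end —
is testable.

## The synthetic cohort: what it emulates, and what it does not

The generator mirrors the study design the pipeline targets: two groups
(default 30 + 30; a study-scale 74/50 cohort is one configuration away),
90 regions, 216 volumes per signal, and cognitive scores drawn from the
published per-group means and SDs (RAVLT, CTMT 1–5, COWA, plus the
self-report BRIEF and PRMQ, a distress score, and Bernoulli minority
status at 33%/20%).

**Region signals** are exact fractional Gaussian noise (fGn), generated
by circulant embedding (Davies–Harte), so the true Hurst exponent of
every signal is known exactly — the property the estimator-recovery
tests rely on. Signals are mixed through a block (community) structure:
region r in block b is
$$x_r = \sqrt{v}\,g + \sqrt{w - v}\,f_b + \sqrt{1 - w}\,e_r,$$
with global factor $g$, block factor $f_b$ and idiosyncratic noise
$e_r$, all fGn, giving expected correlation $w$ within and $v$ between
blocks (defaults 0.5 / 0.1, six blocks of 15 regions). True per-group
Hurst means default to 0.19 (patients) vs 0.22 (controls) — the
published per-group summary, which is an SD-confounded gap, a caveat the
truth manifest records — with a 0.08 between-subject SD so the
between-subject spread matches the printed ~0.10.

**Gray-matter volumes** are a shared smooth template plus a parcel-level
additive group effect plus smooth subject noise, clipped to [0, 1], on a
20x24x20 voxel grid (3 mm voxels) partitioned into 90 parcels; the edges
of the grid taper to background so that mask variation across subjects
produces the network-size variance the statistics covary out. The
published analysis smoothed real morphometry at 12 mm; here smoothness
is simply a generative parameter (Gaussian filtering of white fields,
default width 2 voxels).

**The coupling injection.** The study design the package targets reports
a *negative* correlation between structural and functional clustering in
patients only. The generator injects this with one latent standard
normal factor $z_i$ per patient: the subject's within-block signal
correlation moves with $-z_i$ (driving functional clustering) while the
subject's gray-matter noise smoothness moves with $+z_i$ on the log
scale (driving structural clustering). In controls the two drivers are
independent draws. The driver gains (`fc_corr_gain = 0.18`,
`sc_smooth_gain = 0.55`, `gm_noise_sd = 0.12`) were chosen at design
time so the realized patient-group correlation between the two global
clustering coefficients is about −0.75 — strong but within the range
reported for structure–function coupling effects — which gives the
25-replicate Fisher-comparison detection check its configured effect
size. `coupling = 0` yields a null cohort.

What the generator does **not** emulate: hemodynamics, scanner and
physiological noise, motion, registration error, realistic anatomy, or
any preprocessing chain. Passing tests therefore show that the
*computational pipeline* recovers known effects from data with the
stated statistical structure — not that it would survive the artifacts
of real acquisitions, which upstream preprocessing is assumed to have
handled.

## The Hurst estimator in detail

For a series of length $T$ the analysis length is the natural number
$M \le T$ with the most divisors (ties to the largest such $M$;
`select_window_base(216)` is 180, with 18 divisors), so that every
window size divides the data evenly. For each divisor $d$ of $M$ with
$\max(8, M/16) \le d \le M/2$, the series is cut into $M/d$
non-overlapping segments; each segment contributes
$R/S = (\max - \min)(\text{cumulative mean deviations}) / \sigma$, and
the segment mean $\overline{R/S}_d$ enters the regression
$$\hat H = 0.5 + \text{slope}\left[\log_2 \overline{R/S}_d -
  \log_2 E(R/S)_d \;\sim\; \log_2 d\right],$$
where $E(R/S)_d$ is the Anis–Lloyd expectation with the Peters
finite-sample prefactor — the classical small-sample correction that
anchors white noise at $\hat H \approx 0.5$ even at $T = 216$.

Two numerical choices depart from the most literal textbook recipe, both
for measured bias reasons:

* **Window floor $\max(8, M/16)$ rather than a fixed 8.** Windows much
  shorter than the series carry a finite-window distortion of $R/S$ that
  the $H = 0.5$ expectation subtraction removes only at the null; with a
  fixed floor of 8 the estimator recovers $H = 0.8$ at $T = 4096$ as
  roughly 0.72, while the proportional floor recovers it as about 0.77
  with the null ($T = 216$) still at 0.48.
* **Delta-method log correction.** $E[\log \bar X] \approx \log E[\bar X]
  - \mathrm{Var}(\bar X)/(2 E[\bar X]^2)$; the correction term is added
  back so window sizes with few segments (large $d$) do not drag the
  slope down.
* **Gamma ratio on the log scale.** The Peters prefactor
  $\Gamma((n-1)/2)/(\sqrt{\pi}\,\Gamma(n/2))$ is evaluated via
  `lgamma()`, which is stable at any $n$; the traditional switch to the
  asymptotic $(n\pi/2)^{-1/2}$ above $n = 340$ introduces a non-monotone
  jump in $E(R/S)_n$ and is not used.

Like all rescaled-range estimators this one retains some shrinkage
toward 0.5 at strong persistence; the monotonicity of recovered vs true
$H$ is tested, and group contrasts (the downstream use) are preserved.
Regions whose estimate fails (constant signal) are reported missing and
excluded from the subject's global mean, with a count.

## Thresholding and clustering choices

* *Minimum connection density* is not universally defined; here it is
  the maximum over subjects of the per-subject smallest density at which
  the top-weight edge set connects the graph, computed per modality by
  default (a single common density is available via
  `density_policy = "common"`).
* Thresholding keeps the $\lfloor \rho \cdot N(N-1)/2 \rfloor$ strongest
  *positive* edges; negative correlations are excluded before ranking,
  the usual convention for correlation graphs. Ties break by (row,
  column) order, which makes the edge set — and therefore the density
  search — fully deterministic.
* Clustering is binary after thresholding ("ratio of actual to possible
  connections among neighbors"); nodes of degree < 2 count 0, keeping
  the global mean defined over all nodes.
* Cube inclusion uses a majority-gray rule: a cube is a node iff at
  least 14 of its 27 voxels exceed the density threshold (default 0.1).
  The rule, with its two knobs exposed, approximates "cubes spanning the
  gray matter" while excluding background.
* Cube similarity defaults to the plain 27-value Pearson correlation;
  maximization over the 48 right-angle rotations/reflections of one cube
  (the variant of the originating similarity-network method) is
  available with `use_rotations = TRUE` but off by default for speed and
  transparency.
* A gray-matter mask can be subject-specific (default) or shared; the
  subject-specific mask is what makes network size vary across subjects,
  which the structural GLMs covary out.

## Statistical layer choices

* The GLM group F test is computed by full-vs-reduced model comparison,
  which is contrast-coding invariant for a two-level factor, and matches
  a normal-equations oracle to 1e-8 in tests.
* The Wilcoxon test uses the tie-corrected normal approximation without
  continuity correction, so a reported U of 1271 with groups 65/50
  reproduces p = .046 exactly as printed.
* The FDR family covers the ten performance measures; self-report scales
  are modeled (with the distress covariate) but kept outside the family,
  mirroring how such tables are usually reported.
* The Mahalanobis composite uses the *control-group* mean and unbiased
  covariance — the distance is deviance from controls — over the four
  tests that typically survive FDR (RAVLT total and interference, CTMT
  trial 1, COWA), configurable; distances are floored at 1e-12 before
  the natural log so a patient exactly at the control mean stays finite.
* The two-metric PCA z-scores both clustering columns across all
  participants and eigendecomposes their 2x2 correlation matrix; the
  first component is oriented with a positive structural loading, and
  its variance fraction is exactly $(1 + |r|)/2$ — the identity behind
  the reported "59% of variance" at $|r| = 0.18$.
* For the structural-clustering vs Hurst pair the battery reports both
  Pearson and (on request) Spearman inference, since a printed p of
  .050 at r = 0.26, n = 65 is consistent with a rank correlation but
  not with the Pearson t test (p ≈ .036).

## Problem sizes and determinism

The default cohort (30 + 30 subjects, 20x24x20 grid, ~270 cube nodes)
runs the full pipeline in well under a minute of simulation plus a few
seconds per stage on a laptop core; it was chosen so the calibration
suites (500-replicate Hurst null, 200-replicate type-I error,
25-replicate detection) remain desk-scale. Study-scale settings
(74/50 subjects, a grid yielding thousands of cubes) are configuration
choices; the pairwise cube similarity cost grows quadratically in the
node count.

Every random quantity derives from one master seed through hashed
per-component sub-seeds, so a cohort is byte-reproducible from its JSON
config echo (`write_cohort()` / `read_cohort()` round-trips exactly),
and `run_pipeline()` is idempotent at a fixed seed, recording a config
hash, the densities, and every file it writes in a provenance record.

## Known limitations

* The rescaled-range estimator's residual shrinkage at extreme H (above
  ~0.85 or below ~0.15) means absolute H values are conservative;
  contrasts are the supported inference.
* The divisor-maximizing window base discards $T - M$ trailing points
  (36 of 216 at the default length).
* The similarity-network stage streams whole standardized matrices; at
  study scale (~8,500 nodes) the similarity matrix alone is ~0.5 GB and
  the density search dominates runtime.
* The generator's group effects enter additively and independently per
  parcel; it does not model spatially correlated disease effects or
  site/scanner batch structure.
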