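---
title: "Mapping BOLD signal variability and relating it to behavior with PLS"
author: "boldvar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping BOLD signal variability and relating it to behavior with PLS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boldvar)
```

## The analysis

Moment-to-moment variability of the resting BOLD signal is itself a
meaningful individual-differences measure: per voxel, the standard deviation
of the (denoised, filtered) time series — BOLD-SD — indexes the dynamic range
of regional activity. `boldvar` implements the full chain from denoised 4D
volumes to a multivariate brain-behavior model:

1. **Variability maps.** Each scan is rescaled so its in-mask grand mean
   (over all voxels and timepoints) is exactly 100; BOLD-SD values are then
   comparable across subjects. Per voxel, the temporal mean is subtracted
   and the SD computed. The mean square successive difference (MSSD, the
   classical von Neumann statistic: the mean of squared lag-1 differences,
   not halved, not square-rooted) is available as an alternative metric; on
   realistic autocorrelated series the two track each other closely
   (r > 0.90 across voxels).
2. **Confound removal.** Age and mean framewise displacement (FD) are
   regressed out of every voxel column of the brain block, and age out of
   every behavioral score, by ordinary least squares on an intercept plus
   all confounds jointly. Joint regression makes the result independent of
   confound order; residualization is idempotent and leaves residuals
   orthogonal to the confound span. An unadjusted variant (FD only removed
   from the brain block, behavior untouched) supports analyses restricted to
   a younger subsample, where age adjustment would remove the effect of
   interest.
3. **Behavioral PLS.** With brain block $X$ (subjects × voxels) and behavior
   block $Y$ (subjects × measures), both column-standardized, the
   cross-block matrix $R = Y^\top X / (n-1)$ holds the Pearson correlation
   of every (measure, voxel) pair. Its SVD $R = U S V^\top$ yields
   orthogonal latent variables (LVs): behavior saliences $U$, voxel
   saliences $V$, and singular values $s_k$ whose squared share
   $s_k^2 / \sum_j s_j^2$ is the covariance explained by LV $k$. Brain
   scores are $X_z V$: one number per subject per LV expressing how strongly
   the subject shows the LV's spatial pattern.
4. **Inference.** LV significance: behavior rows are permuted relative to
   brain rows (1000 resamples by default), the whole matrix-and-SVD pipeline
   is recomputed, and $p_k = (\#\{s_k^{perm} \ge s_k\} + 1)/(N+1)$ — the
   add-one convention whose smallest value is $1/(N+1)$. Salience stability:
   subjects are resampled with replacement (1000 resamples), the pipeline is
   recomputed per resample including column standardization, and each
   voxel's bootstrap ratio (BSR) is its original salience over the bootstrap
   SE — a t-like statistic. Brain-score/behavior correlations get percentile
   bootstrap 95% CIs; a correlation is flagged robust when its CI excludes
   zero.
5. **Reporting.** BSR maps are thresholded at |BSR| ≥ 2.5 and cleaned with a
   15-voxel cluster minimum; connected components are extracted separately
   for positive and negative voxels (sign encodes correlation direction) and
   summarized by size and peak coordinates. Overlaying the significance mask
   on a parcellation (e.g. a 200-parcel, seven-network functional atlas plus
   anatomically defined cerebellum, medial-temporal and subcortical groups)
   gives each network's contribution as significant voxels over total
   voxels.

Chronotype utilities round out the behavior block: MEQ global scores
(16-86) map onto the conventional five categories (16-30 definitely
evening, 31-41 moderately evening, 42-58 neutral, 59-69 moderately morning,
70-86 definitely morning, all edges inclusive), and the synchrony score
$s_i = 1 - |z(\mathrm{MEQ})_i - z(24 - t_i)|$ quantifies how well scan time
$t_i$ (24-h decimal hours, reflected so larger means earlier) matched the
subject's chronotype; both z-scores are computed across the analysis sample
itself.

## A worked example on synthetic data

```{r example}
cfg <- generatorConfig(nSubjects = 150, gridShape = c(10, 10, 20),
                       nBehaviors = 22, latentRank = 1, effectSize = 10,
                       confoundStrengthAge = 0.02, seed = 7)
ds <- generateDataset(cfg)
blocks <- prepareBlocks(ds$sd, ds$behavior, adjust = TRUE)
res <- runBehavioralPLS(blocks$sd, buildBehaviorBlock(blocks$behavior),
                        nPermutations = 200, nBootstrap = 200, seed = 11)
res
abs(cor(voxelSaliences(res)[, 1], ds$truth@voxelSaliencesTrue[, 1]))
```

```{r report}
rep1 <- lvReport(res, thresholdSpec(minClusterVoxels = 5), lv = 1)
head(rep1$behaviorCorrelations)
rep1$clusters
```

## The synthetic-data generator

The generator is first-class, tested code: it is the source of every ground
truth the test suite recovers. It plants

- latent scores $Z$ (subjects × rank, columns standardized to mean 0, SD 1),
- voxel saliences $U$ with unit-norm columns supported on a configurable
  fraction of voxels (default 20%), and unit-norm behavior weights $W$,
- a brain block $\mathrm{SD}_{iv} = b_v + e \cdot 0.25\,(ZU^\top)_{iv} +
  \sigma_B \varepsilon$, floored at 0.01, with log-normal baseline $b_v$
  (median 2 normalized BOLD-SD units — the scale real grand-mean-100 data
  occupy),
- a behavior block $Y_{ib} = 50 + e \cdot 10\,(ZW^\top)_{ib} + \sigma_Y
  \varepsilon$ in T-score-like units (mean 50, SD 10, mirroring
  standardized socioemotional scales),
- confounds: age uniform on 20-86 years (the sampled adult range) and mean
  FD log-normal around 0.15 mm, both centered and added to every column of
  both blocks at `confoundStrength * (block reference scale)` per unit.

Two conventions matter. First, the latent amplitude is anchored to fixed
reference scales (0.25 BOLD-SD units, 10 T-score units — the default noise
SDs), so `effectSize` is exactly the signal-to-noise ratio at the default
noise levels, yet setting a noise SD to zero leaves the planted structure
intact and makes oracle tests exact. Second, emitted AR(1) time series are
rescaled post hoc so each voxel's sample SD equals its target value to
machine precision, removing Monte-Carlo slack from every test that compares
computed maps against the planted truth.

What the generator does **not** emulate: scanner artifacts, motion and its
spatial structure, physiological noise, spatial smoothness of real maps,
non-Gaussian score distributions, or the ICA-based denoising applied to real
data. Passing recovery tests therefore demonstrate the estimator chain is
correct and calibrated under the stated model, not that real data meet that
model.

## Numerical and design choices

- **SD denominator.** Sample (n−1) by default, switchable to n; the
  originating toolbox's choice is not documented, so the conventional
  estimator is used and exposed.
- **Grand-mean normalization** runs over in-mask voxels only; including
  background air would let near-zero voxels dominate the scaling. The
  target (100) and the mask are explicit arguments.
- **Correlation vs covariance mode.** The cross-block matrix defaults to
  column-standardized blocks (correlation PLS), the behavioral-PLS toolbox
  convention; raw covariance is a switch. Truth-recovery tests use
  covariance mode: per-column standardization rescales a planted salience
  pattern voxel-wise (strongly driven voxels are compressed toward ±1), so
  only covariance mode preserves planted amplitudes as the effect size
  grows. Both modes share every other code path.
- **Sign conventions.** SVD columns are reflected so each LV's
  largest-magnitude behavior salience is positive (deterministic across
  platforms). Bootstrap resamples are aligned to the original decomposition
  by the sign of the voxel-salience dot product per LV; full orthogonal
  Procrustes alignment is available as an option. Neither rotation is
  applied inside the permutation loop: the k-th permuted singular value is
  compared with the k-th observed.
- **p-value convention.** $(k+1)/(N+1)$, so 1000 permutations bottom out at
  0.001 and p is never zero.
- **Stable-salience sentinel.** When a voxel's bootstrap SE falls below
  1e-6 (saliences are unit-norm, so genuine resampling variability sits far
  above this while SVD round-off sits below it), the BSR is reported as
  signed `Inf` with a `stableMask` flag rather than an overflowed ratio.
- **Degenerate resamples.** A bootstrap draw in which any column loses all
  variance is redrawn and counted (`nRedrawn`), keeping the nominal number
  of resamples.
- **Cluster connectivity** defaults to 26 (vertex-adjacent), the common
  volumetric convention; 6 and 18 are available, and the choice changes
  cluster counts, so it is recorded in the report. Opposite-signed voxels
  never merge. Cluster tables break peak ties deterministically (lowest
  linear index).
- **Missing data** are rejected, not imputed: the analyses this package
  reproduces use complete samples, and silent imputation would change
  inference.
- **Determinism.** All resampling flows from one user seed through a fixed
  integer splitting scheme (permutation and bootstrap streams are
  independent); reruns are bit-identical. Joint row permutation of both
  blocks leaves observed singular values exactly invariant; permutation
  p-values are invariant in distribution (the seeded index stream cannot be
  invariant realization-by-realization).

## Problem sizes

The test suite validates at desk scale, chosen so the full run completes in
well under a minute apart from the calibration blocks: oracle equivalence on
100 scans of 10×10×10×297; permutation calibration on 200 null datasets of
60 subjects × 200 voxels × 8 behaviors at 200 permutations; parameter
recovery at 150 subjects × 2000 voxels × 22 behaviors with 1000
permutations; confound-removal calibration on 50 replicate datasets × two
adjustment arms. Sample sizes mirror the scale of the motivating study (157
adults, ~78 in the younger subsample); voxel counts are reduced from
whole-brain (~150k at 4 mm) to grids that keep SVD and resampling cheap,
which leaves statistical calibration unchanged because every estimator
operates column-wise or on the (small) behavior dimension.

## Limitations

- The pipeline consumes *denoised* data; no motion correction, filtering or
  ICA cleanup is performed or checked.
- Percentile bootstrap CIs are first-order; no BCa correction.
- One peak is reported per connected cluster; subdividing a cluster by
  anatomy requires an external label atlas.
- Covariance explained is always reported over all min(measures, voxels)
  LVs.
- Reproducing the published full-sample figures requires the deposited
  subject-level dataset, which must be obtained separately (see README).
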