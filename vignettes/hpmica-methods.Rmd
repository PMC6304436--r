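---
title: "Methods: hierarchical partner matching ICA, Granger causality, and connectome classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hierarchical partner matching ICA, Granger causality, and connectome classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Spatial independent component analysis (ICA) decomposes a single subject's
resting-state fMRI run into spatial maps that are maximally independent
across voxels, each paired with a mixing time course. Used per subject, it
is data-driven — no seed region, no atlas — but it has three practical
pathologies: the number of components must be fixed in advance, the output
order and the reached optimum vary with the random initialization, and
nothing links component 7 of one subject to component 7 of another.
`hpmica` implements a three-level hierarchical partner matching workflow
that addresses all three, then uses the surviving components for two kinds
of connectivity features — functional (the component z-maps themselves) and
effective (directed Granger causality between component time courses) —
and classifies the fused per-subject feature matrix with a small
convolutional network under leave-one-out cross-validation (LOOCV).

# The three levels

**Level 0 — model order.** The component-number range L is estimated by
AIC and MDL model-order criteria on the eigenvalue spectrum of the
time-by-time covariance (voxels are the observations, matching the spatial
ICA orientation). The range spans the two estimates, rounded outward to a
step grid with at most 12 settings. The criteria assume i.i.d. voxels; no
spatial-smoothness correction is applied. The reference configuration uses
L = 20 to 130 in steps of 10.

**Level 1 — within subject.** ICA is restarted `nRuns` times (default 10)
per subject per setting. Restarts are pooled and clustered by density
peaks: with pairwise distance $d_{ij} = 1 - |r_{ij}|$ (Pearson correlation
over masked voxels; the absolute value absorbs residual sign ambiguity),
local density $\rho_i = \sum_{j \ne i} \exp(-(d_{ij}/d_c)^2)$ with $d_c$
the 2% quantile of the off-diagonal distances, and $\delta_i$ the distance
to the nearest higher-density point. The top K = n + 10 points by
$\gamma = \rho\,\delta$ are centers; other points inherit the label of
their nearest higher-density neighbor. Every non-singleton cluster yields
a group map (GM), the voxelwise one-sample t over its members.

**Level 2 — across subjects.** GMs of all subjects at one setting are
partner-matched: pair (i, j) survives only if each is the other's most
Tanimoto-similar map (mutual argmax). Tanimoto similarity
$T = a\!\cdot\!b / (\lVert a\rVert^2 + \lVert b\rVert^2 - a\!\cdot\!b)$
is computed on rectified maps (negative z-values clipped to zero),
preserving the gradation of activation rather than binarizing. Matches
over all subject pairs form a graph; connected components are clusters,
pruned so that each subject contributes at most one map (the member with
the highest mean similarity to the rest stays). Clusters spanning fewer
than `minOwnerFraction` (default 0.75) of subjects are dropped. Each
cluster yields a cluster map (CM), again a one-sample t-map.

**Level 3 — across settings.** The per-setting CM collections are
partner-matched the same way, with settings as owners. Spatially
overlapping level-3 clusters (any member pair with T > 0.5) compete, and
the one with the highest Cronbach's alpha — maps as items, voxels as
observations — survives. Winners below `minAlpha` = 0.7, the conventional
acceptable-reliability threshold, are discarded: restart-stable noise can
chain through mutual-argmax matching into a formally valid cluster, but
its members do not co-vary over voxels and its alpha sits far below that
of a genuine component. A manual exclusion list by cluster id remains
available for artifacts that pass the floor. Backward tracing
(CM → GMs → ICs) then averages each subject's contributing ICs voxelwise
and re-z-scores, giving one reliable IC per subject per retained cluster.

Two owner-fraction defaults differ deliberately: at level 2 a component
should be present in most subjects (0.75), but at level 3 a genuine
network cannot appear at a setting below the true source count, so
requiring presence at every model order would punish the data for the
grid; the level-3 default is 0.5 (at least half of the settings).

# Effective connectivity

For components X and Y with zero-mean time courses, the restricted model
$X(t) = \sum_{i=1}^{P}\alpha_i X(t-i) + \varepsilon_X$ and the augmented
model $X(t) = \sum_i \alpha_i X(t-i) + \sum_j \beta_j Y(t-j) +
\varepsilon_{XY}$ are both fit by ordinary least squares on the common
sample window $t = P+1,\dots,T$, and

$$\mathrm{GCI}_{Y \to X} = 1 - \frac{\mathrm{var}(\varepsilon_{XY})}
{\mathrm{var}(\varepsilon_X)}.$$

The variance ratio is implemented as the plain ratio of residual sums of
squares on that common window, so $0 \le \mathrm{GCI} < 1$ holds
structurally (nested least squares cannot increase the RSS); the per-fit
variances with the $T-P$ divisor are kept for diagnostics only. The AR
order defaults to P = 1 — at a repetition time of 2 s the hemodynamic
signal carries little reliable structure beyond one lag — with a
BIC-based selector (`p = "bic"`, orders 1–5) available. Time courses are
extracted by spatially regressing each frame onto the component map, so
training and test subjects share one code path; the mixing-matrix column
is equivalent for training subjects. The GCI matrix has an undefined (NA)
diagonal: self-causation is not meaningful, and the diagonal is later
replaced by functional features.

# Features and the classifier

Per retained component, the per-subject reliable IC maps enter a
voxelwise linear model (value ~ group + age + sex; two-sided t with
df = n − 4). Voxels with p < 0.05, uncorrected, form the component's ROI —
deliberately uncorrected, following the reference analysis; with constant
covariates the model reduces exactly to the two-sample t-test. A
subject's functional feature per component is the mean z-value over the
ROI (max |z| is available). Fusion writes these features onto the GCI
diagonal, giving an m × m finite matrix per subject.

The classifier is a small directed-acyclic-graph convolutional network:
conv 5×5 (16 filters) → BN → ReLU → conv 3×3 (32) → BN → ReLU →
conv 3×3 (32) → BN → add(skip: 1×1 conv, 32 filters, tapped after the
first ReLU) → ReLU → 3×3 average pooling, stride 2 → fully connected (2)
→ softmax. All convolutions are stride-1 with "same" padding so the skip
and main branches agree at the merge; the canonical residual wiring (tap
after ReLU 1, merge before the final ReLU) was chosen where the layer
graph was not fully pinned, and is configurable. Training is SGD with
momentum 0.9 (the framework-default optimizer; unstated in the reference)
and cross-entropy loss, 20 epochs, batch 20, learning rate 0.01 dropped
×0.1 every 10 epochs, no augmentation and no early stopping.
Batch-normalization statistics are finalized with one pass over the full
training set after the last epoch, so single-subject prediction uses
stable statistics. Setting `skipConnection = FALSE` yields the plain
sequential ablation.

At test time the held-out subject never touches cluster retention, ROI
definition, or training. Its pooled ICA maps are matched to each training
component by minimal Euclidean distance between z-maps (sign-aligned);
duplicate or distant matches are flagged. The matched maps then follow
the same feature path.

# The synthetic cohort generator

Ground truth for every stage comes from `synthesizeCohort()`: spatial
sources are isotropic Gaussian blobs (peak = amplitude, sd = radius) on a
16 × 16 × 8 grid — five blobs of radius 2 by default — mixed linearly with
time courses from a stationary VAR(1) (self-lags 0.35, two baseline
directed edges of 0.3) driven by Laplace innovations, because spatial ICA
requires non-Gaussian sources; Gaussian innovations are available for
Granger-only work. Subjects get Gaussian blob-center jitter (sd 0.5
voxels), multiplicative log-normal amplitude jitter (sdlog 0.1) and
Gaussian sensor noise (sd 0.25 signal units); 120 timepoints at a
recorded-but-unused TR of 2 s; 10 subjects per group by default. Group
differences are planted as per-source amplitude shifts and per-edge VAR
coefficient deltas (both groups' systems are checked for stationarity).
`separatedCohortSpec()` plants strong differences (+1.5 amplitude on two
sources, three extra directed edges of ~0.5) for classification
benchmarks. Age and sex covariates are drawn with no effect on the data.

What the generator does **not** emulate: hemodynamic-response
convolution, physiological noise, motion, field inhomogeneity, anatomical
variability beyond blob jitter, and spatial autocorrelation of the sensor
noise. Passing tests therefore demonstrate the algorithmic contracts —
recovery, correspondence, calibration, leakage-freedom — not performance
on clinical data.

# Numerical choices

- **Duplicate tolerance in density peaks.** ICA restarts of one subject
  converge to the same optimum up to the fixed-point tolerance; the
  resulting map distances (~1e-8 to 1e-5) are numerical scatter, not
  structure. Distances at or below `duplicateTol` = 1e-4 are treated as
  exact duplicates, and a kernel width $d_c$ that lands in the duplicate
  mass falls back to the smallest positive distance. Without this, the 2%
  quantile collapses to the scatter scale and clouds fragment.
- **Variance floor in t-maps.** The one-sample t is computed as
  $t = \bar x / \sqrt{(s^2 + s_0^2)/m}$ with $s_0$ = 0.01, i.e. 1% of the
  unit scale of z-scored maps. Below the floor (near-duplicate members) t
  is proportional to the mean map instead of amplifying 1/s noise; above
  it the ordinary t is recovered to within ~1e-3 for |t| ≈ 5. This also
  keeps sd = 0 voxels finite; their count is recorded.
- **Tie-breaking** is lowest-index-wins everywhere (density ordering,
  nearest neighbors, argmax), making runs bitwise reproducible.
- **Seeds.** Every stochastic step derives its seed from the master seed
  with a fixed integer mix kept below 2^31; identical seeds give
  byte-identical outputs.
- **Degenerate inputs.** Constant maps are rejected by name; all-zero
  rectified map pairs get similarity 0 with a warning; zero restricted
  residual variance flags the GCI as undefined; empty ROIs yield feature
  0 with a flag; subjects absent from a retained cluster are marked
  missing, excluded from that component's group test, and contribute 0
  features.

# Cross-validation design

Per-subject ICA restarts and level-1 clustering depend only on that
subject's data, so they are computed once (`precomputeSubjectMaps()`) and
shared across folds; every cross-subject quantity — level-2/3 matching,
alpha selection, ROI masks, network weights — is recomputed per fold from
the n − 1 training subjects. The desk profile trains with batch 5: at
n ≈ 20 this keeps roughly three gradient updates per epoch, the same
regime as the reference protocol (67 training subjects at batch 20); with
batch 20 the network would receive a single update per epoch and
underfit.

A note on the label-permutation control: LOOCV accuracy under shuffled
labels is expected slightly *below* 0.5 with balanced classes, because
each fold's training set then carries a majority of the opposite class of
the held-out subject. Within-shuffle predictions are also dependent. The
permutation check therefore bounds the null accuracy above by the pooled
binomial band (the leakage-sensitive direction) and below only at
single-run binomial precision.

# Problem sizes

The bundled checks run on 16 × 16 × 8 grids with 120 timepoints, 5
sources, L = {4, 6, 8}, 5–10 restarts and cohorts of 8–20 subjects; the
classifier input is then 5 × 5 to 6 × 6 rather than the reference 24 ×
24, which the architecture accommodates (pooling leaves a 2 × 2 map). The
reference configuration (20–130 components, 10 restarts, 24 × 24 fusion)
ships as the `"reference"` profile and is audited by a configuration snapshot
test.

# Limitations

- Individual (not group) ICA only; no dual regression or
  back-reconstruction.
- Pairwise (not conditional) Granger causality, time domain only, no
  hemodynamic deconvolution, no edge-level significance testing.
- No multiple-testing correction in the ROI stage, by design.
- The alpha item/observation orientation treats maps as items; the
  alternative orientation is not implemented.
- Desk-scale synthetic validation cannot certify clinical performance;
  the headline numbers of the motivating analysis depend on a private
  cohort and are out of reach by construction.
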