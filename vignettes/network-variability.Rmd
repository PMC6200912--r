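---
title: "Quantifying test-retest variability of resting-state networks on parcellated connectomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying test-retest variability of resting-state networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rsnvar)
```

## Scope and model

`rsnvar` analyzes two resting-state fMRI acquisitions of one session, both
reduced to a T×N region-by-time matrix on a fixed parcellation, and asks how
stable each of nine canonical resting-state networks (auditory, DMN, ECNL,
ECNR, salience, sensorimotor, VL, VM, VO) is between the two runs. The
pipeline is:

1. **Motion regression.** Per region, residuals of an OLS fit on an
   intercept plus the six rigid-body realignment parameters. Motion is also
   summarized by the mean displacement Δ (time-average of the root sum of
   squares of the six parameters) and the displacement speed Σ (the same
   statistic on per-TR differences). Both follow the conventional formulas
   literally: translations in mm and rotations in degrees are pooled in
   quadrature *without* unit conversion. An optional conversion of degrees
   to mm of arc on a 50 mm sphere exists (`rot_to_mm = TRUE`) but is off by
   default, for fidelity to the printed definition.
2. **Spatial ICA.** The series is modeled as X = A·S with S a k×N matrix of
   spatially independent component maps. Sources are extracted by symmetric
   fixed-point FastICA (logcosh contrast) on PCA-whitened data. The
   orthonormal initial rotation is drawn from the user's seed, making the
   decomposition deterministic per seed. Sign indeterminacy is fixed by
   flipping each component so its spatial skewness is nonnegative; each map
   is standardized to mean 0, sd 1 over regions before any graph use.
3. **Fingerprint classification.** Eleven features per component: degree of
   clustering, spatial skewness, spatial kurtosis, spatial entropy, one-lag
   autocorrelation, temporal entropy, and the periodogram power fractions of
   five bands (0–0.008, 0.008–0.02, 0.02–0.05, 0.05–0.1, 0.1–0.25 Hz). The
   default neuronal rule: the low-frequency fraction must exceed the
   high-frequency fraction and spatial kurtosis must stay below a ceiling.
4. **Template matching.** Each network is assigned the component maximizing
   goodness-of-fit — mean z inside the binary template minus mean z outside —
   under a greedy *exclusive* scheme over all (network, component) pairs
   simultaneously, so no component serves two networks.
5. **Graph strength and ROF.** Edge weight w_ij = |z_i| + |z_j| − |z_i −
   z_j|, normalized to [0, 1], averaged over the 101-threshold sweep, summed
   into node strengths. Regions strictly above half the network's maximum
   strength are compared with the template mask: ROF = (in − out)/mask size.
6. **Variability and best acquisition.** ΔROF = ROF_T1 − ROF_T2 with a
   missing acquisition contributing 0; mean |ΔROF| over all nine networks
   summarizes the session; per network the neuronal acquisition with higher
   ROF is the "best finding". The per-region maximum graph strength over
   neuronal networks, z-scored, is correlated with the z-scored regional PET
   uptake (two-sided p from the t transform with N−2 degrees of freedom).

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `k` (ICA order) | 30 | components | standard order for a ~1000-region parcellation; see model-order note below |
| neuronal band | 0.01–0.05 | Hz | canonical BOLD band for neuronal signal |
| artifact band | 0.1–0.25 | Hz | cardio-respiratory and scanner artifact range at TR = 1 s |
| `kurtosis_ceiling` | 50 | – | rejects single-spike maps only; planted indicator maps sit near 10 |
| threshold grid | 0–1 step 0.01 | – | 101 thresholds, keep entries ≥ t |
| half-max selection | strict `> max/2` | – | a region exactly at half max is excluded |
| z-score / skewness | sample sd (n−1); skewness bias-uncorrected | – | one convention had to be chosen; both documented and tested |
| entropies | 32-bin histograms | nats | stable at T = 480, N ≥ 60 |

## Conventions the source material leaves open

Several choices were reverse-engineered or settled here; each is frozen and
tested:

* **ΔROF missing rule and denominator.** When a network is non-neuronal or
  undetected in one acquisition, its ROF contributes 0 to ΔROF, and mean
  |ΔROF| always divides by the full nine networks. This is the only
  convention under which the packaged variability table reproduces all three
  published patient means (0.32 / 0.26 / 0.39) from its printed ROF columns,
  which `run_table1_check()` verifies cell by cell.
* **Threshold ties.** "Keep values greater than the threshold" versus "zero
  values less than the threshold" leaves equality open; `>=` is used so the
  t = 0 threshold is the identity. The closed form `w·(⌊100w⌋+1)/101` is
  implemented with an exact tie correction so it matches the explicit
  101-iteration loop to machine precision even on grid multiples.
* **Normalization.** Weights are normalized per component (not per subject)
  by the matrix maximum; the 0-to-1 grid is meaningless on raw z-derived
  weights. This is an interpretive choice, flagged here deliberately.
* **Goodness-of-fit statistic.** The inside-minus-outside mean of z is the
  literature-standard similarity score for template matching; the exact
  statistic behind the original software is not printed. It is linear in z
  and invariant to additive shifts (tested).
* **Degree of clustering.** Undefined in the source material. The pipeline
  is parcellated end-to-end and carries no voxel adjacency, so the Gini
  concentration of |z| over regions is used as the geometry-free measure of
  spatial concentration.
* **Classification bands.** The neuronal band 0.01–0.05 Hz is not one of the
  five fingerprint bands; classification uses band 2 + band 3
  (0.008–0.05 Hz, the nearest representable superset) against band 5
  (0.1–0.25 Hz). The band printed as "0–008 Hz" is read as 0–0.008 Hz.
* **Classification order.** Networks are assigned first and flagged
  non-neuronal afterwards (present-but-non-neuronal is reportable); the
  reverse order — pass only neuronal components to the matcher — is
  available by supplying `neuronal_flags` to `assign_networks()`.
* **Self-loops.** Node strength excludes the diagonal; the summation
  convention is silent, and node strength conventionally omits self-edges.

## ICA model order

k = 30 is the published operating point for ~1000-region data, where the
spatial sample size (N regions) comfortably supports 30 directions. At the
test scale of N = 60 regions, whitening to 30 dimensions is statistically
unsupported — ICA then splinters sources and mixes noise directions into
maps. The acceptance-scale analyses therefore set k to the true source count
of the simulation (9 networks + 4 artifact sources = 13), which is the
choice a practitioner would make from a scree plot. This is a property of
model-order selection at small N, not of the implementation; recovery at
k = 30 on 1015 regions is the intended regime.

## What the generator emulates — and what it does not

The synthetic world (`sim_config()` defaults): 60 regions, nine disjoint
5-region networks, 480 time points at TR = 1 s (matching the targeted
acquisition protocol: two ~8-minute runs of 480 volumes), band-limited
neuronal sources built by zero-phase DFT-mask filtering of white noise
(0.01–0.05 Hz), four artifact sources band-limited to 0.1–0.25 Hz loading
diffusely on all regions, white measurement noise at amplitude ratio 4
(source:noise), member loadings uniform on [0.8, 1.2], optional leakage onto
non-members, optional linear-drift/jitter motion, and a PET map constructed
as `α·z(max-GS) + √(1−α²)·z(noise)` so its expected correlation with the
ground-truth maximum graph-strength map equals α (default 0.5). All
randomness flows from one seed through an isolated RNG scope; fixed seed
gives bit-identical output.

It deliberately does **not** model: hemodynamic response convolution, EPI/k-
space physics, spatial autocorrelation between neighboring parcels, lesions
or atrophy, physiological noise locked to cardiac/respiratory phase, or
inter-run changes in network topology (both runs plant the same membership,
differing only in loadings and noise). A green end-to-end test therefore
establishes that the pipeline's stages compose correctly and recover planted
structure at realistic SNR — not that the method is robust to the full
pathology of clinical BOLD, and not that the published patient-level r
values (which require the unreleased scans) are reproduced.

## Numerical notes

* Degenerate inputs: constant time courses yield zero band powers and
  autocorrelation with a `degenerate` flag and classify non-neuronal with a
  warning; an all-zero z-map yields an all-zero weight matrix with a
  warning; an all-zero strength map selects no regions with a warning;
  constant vectors are rejected by `zscore()`, `sample_skewness()` and
  `pearson_with_p()` as validation errors.
* Rank-deficient motion designs (e.g. an all-zero trace) are handled by the
  pivoted QR — regression then reduces to demeaning.
* Assignment ties break toward the lower component index, then the earlier
  template; best-acquisition ties go to T1.
* ROF is carried at full precision; 2-decimal rounding happens only in the
  report writer, matching the published presentation.
* NIfTI support is a minimal uncompressed little-endian NIfTI-1 subset
  (int16/int32/float32/float64), sufficient for label images, BOLD and PET
  volumes written by this package; it is not a general-purpose reader.

## Known limitations

Single-subject, descriptive statistics only (no across-patient inference —
the motivating use case has n = 3); no spatial normalization or smoothing
(label image and BOLD must share a grid); infomax is approximated by
FastICA (any deterministic-seeded ICA is contract-compatible); concatenated-
run decompositions can legitimately fail to isolate networks that differ
between runs, which surfaces as `NA` concat ROFs in reports.
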