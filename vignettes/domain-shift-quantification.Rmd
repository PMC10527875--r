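---
title: "Quantifying scanner-induced domain shift in structural MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying scanner-induced domain shift in structural MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Multi-center MRI studies pool scans acquired on different scanners with
different protocols. The resulting *domain shift* — systematic differences
in contrast, noise, resolution and texture between sites — degrades any
model trained on one site and applied to another, and confounds pooled
statistical analyses. Harmonization methods exist, but validating whether
they worked requires a way to *measure* the shift in the first place.

`mrishift` measures domain shift from the images alone. Each scan is reduced
to 22 no-reference quality features; the per-scan feature table is then
analysed with kernel two-sample distances (MMD), cross-validated domain
classification, random-forest feature-importance ranking and 2-D
embeddings. If a classifier can tell sites apart from quality features at
near-perfect accuracy, the cohort carries strong scanner signature;
chance-level accuracy and near-zero MMD indicate homogeneous data.

## The 22 features

Features are computed on 2-D slices taken along the three anatomical planes
of the canonically (RAS) oriented volume, on each slice's foreground `F`
(anatomy) and background `B` (air), and averaged over all retained slices.

**Spatial domain** (per-slice, population variance throughout):

* `MEAN`, `RNG`, `VAR` — mean, range and variance of foreground intensity;
* `CV` — coefficient of variation, sigma_F / mu_F;
* `PSNR` — 10 log10(max(F)^2 / MSE(F, median5(F))), the reference being the
  5x5 median-filtered slice;
* `SNR1` — sigma_F / sigma_B;
* `SNR2` — mu_FP / sigma_B, with FP a seeded random 5x5 foreground patch;
* `CNR` — (mu_FP − mu_BP) / sigma_BP, with BP a background patch;
* `CJV` — (sigma_F + sigma_B) / |mu_F − mu_B|, sensitive to bias fields and
  motion;
* `EFC` — the entropy focus criterion: the Shannon entropy of the intensity
  distribution normalized so that a uniform slice scores 1 and a
  single-pixel impulse scores 0; blur and ghosting raise it.

**Frequency domain**, computed on the background-zeroed slice:

* `SNRF` — the centered 2-D power spectrum is split at one quarter of the
  maximal distance from DC; SNRF = 10 log10 of signal-disc over
  remainder power. The radius fraction is a package convention (the split
  is exposed as `snrf_radius`) pinned by closed-form tests.
* `LFR`, `HFR` — the slice is convolved with a 3x3 Gaussian
  ([1,2,1;2,4,2;1,2,1]/16) or Laplacian ([−1,−1,−1;−1,8,−1;−1,−1,−1])
  kernel (symmetric padding), and the square-rooted FFT amplitude spectrum
  of the result is reduced to its mean over bins. The mean-over-bins
  reduction is the simplest permutation-invariant scalar summary and is
  pinned by the constant-slice closed form: a constant slice c on an N x M
  grid gives LFR = sqrt(c N M) / (N M) and HFR = 0 exactly.

**Wavelet domain**: a single-level separable orthonormal 2-D DWT (periodic
extension; first-order Coiflet by default, with Haar, Daubechies 2/4 and
Symlet 4 selectable) yields all four subbands, from which

* `WCS` — mean magnitude of the coefficients whose magnitude is at least
  the mean magnitude (ties count as significant);
* `WQS` — sum of magnitude x cos(phase); for a real transform this is the
  plain signed coefficient sum, and it is implemented as such;
* `WCE` — mean absolute coefficient.

Since no 2-D wavelet transform is available among the installed R packages,
the DWT is implemented in the package and verified by Parseval identity
(energy conservation to 1e-6 on even-sized inputs) and hand-computed Haar
cases. One decomposition level keeps the transform well-defined on the
smallest admissible slices.

**Texture domain**: the foreground is linearly quantized to 64 grey levels
(background pixels carry an ignore label), a symmetric normalized GLCM is
accumulated at distance 1 and averaged over the four standard angles, and
six Haralick-style properties are derived: contrast, dissimilarity, ASM,
homogeneity, correlation (defined as 1 when a marginal SD vanishes) and
energy = sqrt(ASM). The counting is verified cell-by-cell against a
brute-force pair-counting oracle.

## Foreground detection and slice retention

Each slice is segmented by light 3x3 Gaussian smoothing, Otsu thresholding,
3x3 morphological closing, selection of the largest connected component and
hole filling. Two degenerate regimes are handled explicitly: an all-zero
slice is flagged unusable, and a slice whose exact-zero plateau covers more
than 20% of pixels is treated as preprocessed (skull-stripped or zero-padded)
data, whose anatomy support is the nonzero set itself — Otsu on such slices
would split bright versus dim anatomy rather than anatomy versus air.
Slices whose foreground covers less than 1% of pixels are excluded from
aggregation; near-empty edge slices otherwise destabilize the statistics.

The background noise statistics (sigma_B and the BP patch) are estimated at
least 3 pixels (Chebyshev) away from any foreground pixel
(`bg_erosion = 3`; 0 recovers the raw whole-background definition). The
standoff is the usual air-region noise-estimation practice: without it the
partial-volume / point-spread skirt around the anatomy boundary leaks into
sigma_B and SNR1 stops tracking the acquisition noise level. A background
whose interquartile range is zero (a constant plateau with a few stray
pixels) supports no noise estimate, and the dependent features are recorded
missing rather than absurdly large.

Scan-level aggregation is the unweighted mean of each feature over all
retained slices of all three planes, ignoring missing values, which yields
exactly one 22-vector per scan. Per-slice +Inf flags (zero-error
degenerates) are likewise excluded from the mean. Patch draws are seeded
per (seed, scan, plane, slice), so extraction is fully deterministic.

## Shift analysis

Features are standardized once per table: missing values are imputed by the
column median (so skull-stripped cohorts with missing noise features remain
analysable), then z-scored with population SD; constant columns map to 0.

* **MMD** — the biased (V-statistic) squared maximum mean discrepancy with
  an RBF kernel, `mean(K_aa) + mean(K_bb) − 2 mean(K_ab)`, bandwidth set by
  the median heuristic on the pooled pair unless given. The kernel,
  bandwidth rule and feature scaling are package conventions, fixed and
  documented; absolute MMD magnitudes are therefore only comparable within
  one convention. A useful scale-free summary is the ratio of between-site
  MMD to the split-half MMD within one site.
* **Domain classification** — stratified 5-fold cross-validated mean
  accuracy of a linear SVM (cost 1) and a 500-tree random forest, seeded.
* **Importance** — one seeded 500-tree forest on the full table; Gini
  (impurity) importance normalized to sum 1.
* **Embeddings** — t-SNE (perplexity 30, reduced to (n−1)/3 for small n) and
  UMAP (15 neighbours, min_dist 0.1), seeded; coordinates are deterministic
  given the seed.

`domain_shift()` bundles all four into a classed `shift_report` with
`print`, `summary` and `plot` methods.

## The synthetic multi-site generator

Real multi-center MRI cannot ship with a package, so every pipeline stage
is exercised on synthetic phantoms with analytic ground truth. A phantom is
a centered ellipsoid with semi-axes at 45% of each dimension — a head
fitted to the field of view with an air margin, so that, as in real scans,
almost every slice contains anatomy — built from two nested tissue shells
(relative intensities 0.55 and 1.0, a crude grey/white contrast). A site's
`scanner_profile` applies, in order: a gamma contrast transform on the
normalized template, a smooth low-order polynomial multiplicative bias
field, Gaussian PSF smoothing of the stated FWHM acting within the head
support, and additive Gaussian noise everywhere, so the air region carries
noise only. Per-voxel noise scales as `noise_sd / voxel_size^3`, the
SNR-voxel-volume trade-off of acquisition at otherwise fixed parameters;
`noise_sd` is defined at the 1 mm reference.

Cohorts draw per-volume jitter from seeded sub-streams keyed by
(seed, site, index) — adding a site never perturbs existing volumes — with
about 3% SD on base intensity and ellipsoid axes (anatomy varies between
subjects) and 15% SD on the noise level (coil loading, head size, motion).
The PSF and contrast transform are hardware/protocol properties and stay
fixed within a site.

What the phantom does *not* emulate: Rician noise statistics, k-space
artifacts (ghosting, spike noise), anatomy-dependent texture, pathology,
or registration/interpolation effects. Tests passing on phantoms therefore
demonstrate that the pipeline detects injected acquisition differences of
realistic kind and size, not that it reproduces any particular clinical
cohort's numbers.

## Design of the importance-recovery experiments

A subtlety worth recording: when a single knob separates sites at huge
effect sizes (say noise SD 5 versus 25 with no within-site acquisition
variability), essentially all 22 features become perfect separators. Every
tree then splits purely at the root on whichever perfect feature its `mtry`
sample happens to contain, so Gini importance approaches the uniform
distribution over the separating features, and "which feature ranks first"
is a tie-break, not a measurement. Importance recovery is therefore tested
in non-saturating regimes (25 scans per site): sites differing in noise SD
4 versus 6 (a realistic between-scanner difference, against 15% within-site
noise jitter), where the directly noise-driven features (PSNR, CNR, SNR1,
SNR2) reach the top of the ranking, and PSF FWHM 2 versus 3 mm at noise
SD 1 — low noise, so the blur response is not masked by noise variability —
where HFR does.  Even in these regimes the ranking among the leading
features retains sampling variability across cohort realizations; the
property that holds consistently is top-group membership, not a fixed
first place.
Large contrasts remain excellent for classification and MMD — they are
exactly what the three-site reference cohort uses — they are just the wrong
regime for interpreting a ranking.

## Numerical choices and conventions

* Population (N-divisor) variance everywhere.
* Symmetric (edge-replicating) padding for all small-kernel convolutions
  and the median filter; pinned by zero-response tests on constant slices.
* The PSNR median reference is computed by an exact order-statistics filter
  (compiled); slices equal to their median filter yield the +Inf flag.
* Correlation of a degenerate (constant-image) GLCM is 1 by convention.
* Wavelet filters follow the usual decomposition-filter convention
  (low-pass sums to sqrt(2)); odd slice dimensions are periodized by
  repeating the last sample, so exact Parseval holds for even sizes.
* Missing features are NA, never NaN, and are serialized as empty CSV
  cells; per-feature median imputation happens only at analysis time.
* t-SNE perplexity falls back to (n−1)/3 below n = 91; UMAP neighbour count
  to n−1 below n = 16, each with a message.
* Problem sizes in the test-suite: formula oracles run on 100 random small
  slices per operation; cohort-level checks use 64^3 volumes with 15-50
  scans per site (the three-site reference condition is 30 per site), sizes
  at which all acceptance properties hold with wide margins while the whole
  suite stays comfortably within an ordinary desktop run.

## Known limitations

* MMD magnitudes depend on the kernel/bandwidth/scaling convention; only
  ratios and permutation tests transfer across conventions.
* The foreground detector is a generic Otsu pipeline, not a brain-specific
  segmenter; on heavily artefacted real slices its masks (and hence
  region-based features) inherit its mistakes.
* WQS degenerates to the signed coefficient sum for any real DWT; a complex
  (e.g. dual-tree) transform would be needed for genuine phase.
* Slices are taken in voxel space without resampling to isotropic spacing;
  anisotropic acquisitions therefore weight planes unequally.
* Scan-level features average over slices; within-scan spatial patterns of
  shift (e.g. coil-dependent shading confined to one region) are diluted.
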