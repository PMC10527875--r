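# mrishift

Quantifies **domain shift** — site and scanner effects — in multi-center
structural MRI cohorts, directly from the images.

Pooling MRI from several imaging centers mixes scans whose contrast, noise,
resolution and texture differ systematically with the scanner and protocol.
These acquisition signatures confound pooled analyses and break models
trained at one site and deployed at another, and they survive common
preprocessing such as skull stripping and template registration. `mrishift`
is for researchers who need to know, before (and after) harmonization, *how
much* scanner signature a cohort carries and *which* image properties carry
it.

## What it computes

Every NIfTI volume is reduced to 22 no-reference quality features, computed
slice-wise along the three anatomical planes of the canonically oriented
volume and averaged over retained slices:

| Domain | Features |
|---|---|
| spatial | MEAN, RNG, VAR, CV, PSNR, SNR1, SNR2, CNR, CJV, EFC |
| frequency | SNRF, LFR, HFR |
| wavelet (1-level 2-D DWT, Coiflet-1) | WCS, WQS, WCE |
| texture (64-level GLCM, distance 1, 4 angles) | Contrast, Dissimilarity, ASM, Homogeneity, Correlation, Energy |

with, e.g., SNR1 = sigma_F / sigma_B contrasting foreground and air, the
entropy focus criterion EFC in [0, 1] rising with blur and ghosting, and
HFR the mean square-rooted FFT amplitude after a 3x3 Laplacian.

The scans x features table is then analysed four ways:

* **MMD** — squared maximum mean discrepancy between sites (biased
  V-statistic, RBF kernel, median-heuristic bandwidth on standardized
  features): a kernel two-sample distance that is 0 iff the distributions
  coincide;
* **domain classification** — stratified 5-fold accuracy of a linear SVM
  and a 500-tree random forest predicting the site from the features
  (accuracy near 1 = strong shift, near chance = homogeneous);
* **feature importance** — Gini importance ranking of the 22 features from
  one seeded forest;
* **2-D embeddings** — t-SNE and UMAP maps for visual inspection.

A synthetic multi-site phantom generator (ellipsoid head phantom; per-site
noise, contrast gamma, PSF smoothing, bias field and voxel size) makes the
whole pipeline testable without any data download.

## Worked example

```r
library(mrishift)

profiles <- list(
  scanner_profile("siteA", noise_sd = 5,  contrast_gamma = 1.0, smoothing_fwhm = 2),
  scanner_profile("siteB", noise_sd = 15, contrast_gamma = 1.3, smoothing_fwhm = 4)
)
cohort   <- generate_multisite_cohort(profiles, n_per_site = 10,
                                      shape = c(48, 48, 48), seed = 42)
features <- extract_features(cohort$volumes, labels = cohort$labels, seed = 42)
report   <- domain_shift(features, "site", seed = 42)
report
```

```
Domain-shift report (20 scans, label: site)

Pairwise squared MMD:
       siteA  siteB
siteA 0.0000 1.1092
siteB 1.1092 0.0000

5-fold domain-classification accuracy:
   svm_linear random_forest 
            1             1 

Top 5 features by RF importance:
  VAR            0.060
  EFC            0.060
  ASM            0.060
  SNR2           0.057
  Dissimilarity  0.057
```

Both classifiers separate the two emulated scanners perfectly and the
between-site squared MMD (1.11) is far above the within-site level (a
split-half within one site gives 0.16 here), i.e. this cohort carries a strong
scanner signature. `plot(report)` draws the t-SNE map coloured by site;
`summary(report)` adds per-site counts. With real data, point
`extract_features()` at a directory of `.nii`/`.nii.gz` files plus a
`labels.csv` with `scan_id` and a site/manufacturer column.

A thin command line sits in `inst/cli/mrishift`
(`mrishift simulate | extract | analyze`).

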