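---
title: "How PET auto-segmentation choices propagate into prognostic models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How PET auto-segmentation choices propagate into prognostic models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petrad)
```

## The problem

Radiomic prognostic modelling on FDG PET starts from a delineation of the
metabolic tumour volume (MTV). Automatic segmentation methods disagree —
sometimes substantially — about where the tumour boundary lies, and every
texture feature computed inside the mask inherits that disagreement. When
those features then enter a Cox proportional-hazards model and the model's
linear predictor is used to stratify patients into risk tertiles, two
pipelines that differ only in the segmentation algorithm can place the same
patient in different risk groups. `petrad` implements this entire chain —
phantom simulation, nine delineation algorithms, ten standardised image
features, Cox modelling with backward elimination, tertile stratification
and cross-method concordance — so that the size of the effect can be
measured under controlled, fully known conditions.

## The synthetic data

No public imaging or survival data accompany this problem, so the package
generates its own, with known ground truth at every stage.

**Phantoms.** A lesion is an ellipsoid of elevated uptake (`lesion_mean_suv`,
default 8) on uniform background (default 2 — a tumour-to-background ratio
of 4), with optional zero-mean Gaussian texture inside the lesion
(`heterogeneity_sd`), convolved with a Gaussian point-spread function
(default FWHM 6 mm, the scale of a clinical time-of-flight reconstruction),
plus i.i.d. Gaussian noise (default SD 0.3 SUV), clipped at zero because SUV
is non-negative by definition. The grid uses 2.73 x 2.73 x 3.27 mm voxels.
The ground-truth mask is the pre-blur ellipsoid; its voxel count times the
voxel volume is the reference MTV. Blur is applied before noise — that order
mimics reconstruction smoothing followed by residual noise and is fixed.
These distributional choices are the simplest ones that support
parameter-recovery testing; Gaussian within-lesion texture is *not* a claim
about the statistics of real tumour heterogeneity, which are unknown here.
One lesion per volume; nodal disease, scatter and sinogram-level physics are
out of scope.

**Cohorts.** Patients carry an age (normal, mean 67, SD 10, truncated to
24-84), a radiological stage code 1-8 (multinomial with the stage-group
frequencies of a real oesophageal-cancer staging cohort), a treatment-intent
code (1 = curative, 2 = palliative, P(curative) = 0.525) and three lesion
texture covariates (skewness, excess kurtosis, grey-level non-uniformity).
Overall survival is exponential proportional hazards on the mean-centred
covariates with user-chosen log-hazard coefficients; the baseline hazard
log(2)/17 per month gives a median survival of 17 months at the covariate
means. Censoring is uniform on (0, c); c is solved by `uniroot` so the
expected censored fraction hits the target (default 0.31). Two modes exist
behind one interface: a fast tabular mode that draws the texture covariates
from calibrated distributions (used for the large-n recovery and selection
simulations), and an imaging mode that generates one phantom per patient —
lesion radius, uptake and heterogeneity jittered log-normally — and uses the
features extracted from the *ground-truth* mask as the hazard covariates, so
that a downstream model fitted on *segmented* masks has a real signal to
find, attenuated exactly by whatever the segmentation gets wrong.

## The segmentation methods

All nine methods operate on the SUVs inside a bounding box (in practice the
truth mask dilated by 8 voxels, standing in for a manually placed box), and
every returned MTV is post-filtered to its largest 26-connected component so
scattered background voxels cannot inflate the volume.

* **AT** — adaptive iterative thresholding with background subtraction. The
  background B is the mean of the one-voxel shell just inside the box; the
  threshold iterates `T' = B + w (mean{SUV > T} - B)` from
  `T0 = B + w (SUVmax - B)` with w = 0.5. On a two-level lesion (10 on 2)
  the fixed point is exactly 6.
* **KM2/KM3/KM4** — 1-D k-means (Lloyd). **FCM2** — fuzzy c-means with
  fuzziness m = 2, masking voxels whose top-cluster membership exceeds 0.5.
  **GCM3/GCM4** — 1-D Gaussian-mixture EM with a variance floor (1e-6
  SUV^2), stopping on a log-likelihood gain below 1e-4. In all clustering
  methods the tumour is the highest-mean cluster — the lesion is the hottest
  class by construction.
* **RG** — region growing from the SUV-maximum voxel, admitting
  26-neighbours above a fraction f = 0.6 of the current region mean and
  stopping when a pass adds at most 5% of the region.
* **WT** — watershed on the 3-D Sobel gradient magnitude, computed as the
  minimax cut separating the SUV-maximum voxel from the box-boundary shell
  on the minimum spanning tree of the voxel graph (edge weight = mean
  endpoint gradient). This is the minimum-spanning-forest formulation of the
  marker-based watershed.

Cluster initialisation is deterministic: initial centres are evenly spaced
over the observed SUV range. Quantile-based placement, the other natural
choice, degenerates on lesion-in-box data — with an 8-voxel dilation more
than 95% of box voxels are background, so every quantile centre coincides
with the background value and the iteration can never separate the lesion.
Range spacing has no such failure mode and keeps every method seed-free.

A contour fails the automated screen (`flag_failed_contour`) when it is
empty, occupies at least 20% of the box boundary (the "conformed to the
bounding box" failure mode), or — when ground truth is available — overlaps
it with Dice below 0.30. The 20% and 0.30 thresholds are explicit surrogates
for subjective radiologist review and are configurable. A method is retained
for analysis only if at least 90% of its contours pass.

## The image features

SUVs are discretised with a fixed bin width of 0.5 SUV anchored at 0
(`level = floor(SUV/0.5) + 1`), which keeps intensity resolution constant
across lesions; bins are half-open, so edge values go up. On top of the
discretised mask the package computes: volume, SUVmax, energy (sum of
squared SUVs), population skewness and excess kurtosis, histogram entropy
(base 2), GLCM dissimilarity (13 unique 3-D directions at Chebyshev distance
1, symmetric matrices, unweighted average over directions with at least one
pair), GLSZM grey-level non-uniformity (`sum z_i^2 / N_z` over 26-connected
equal-level zones; the unnormalised variant is a config switch) and zone
percentage (`N_z / N_v`), and NGTDM coarseness
(`1 / (1e-12 + sum p_i s_i)`, the epsilon guarding flat regions, reported as
the 1e12 sentinel there). Whether "kurtosis" means raw or excess is
ambiguous at one decimal of a model coefficient; excess is the default with
`kurtosis_excess = FALSE` available. No image interpolation is applied
before extraction, and no shape features beyond volume are computed. Every
feature is validated against an independent brute-force oracle (exhaustive
triple loops, recursive flood fill) on random 4x4x4 volumes at tolerance
1e-10.

## The modelling chain

Cox models use the partial likelihood with Breslow tie handling (Efron by
config) through `survival::coxph`, summarised as estimate, Wald p, hazard
ratio `exp(estimate)` and CI `exp(estimate +/- 1.96 SE)`. Backward
elimination removes, at each step, the covariate with the largest
likelihood-ratio removal p-value while it exceeds `p_remove = 0.05`
(covariate order breaks ties); this approximates the stepwise
backward-conditional procedure of the major statistics packages. The
prognostic score is the raw linear combination of covariate values and
coefficients — age in years, treatment 1/2, stage 1-8 entered as a single
ordinal term (a single printed coefficient per model forces ordinal
treatment even though staging is conceptually categorical; this is a known
modelling compromise), plus whatever texture features survived elimination.
Patients are ranked by score and cut at ranks ceiling(n/3) and
ceiling(2n/3) into low/intermediate/high groups; boundary ties go to the
lower-risk group, so sizes can deviate from n/3 and are reported. With 427
distinct scores the rule gives 143/142/142.

Concordance between methods is the count (and percentage, 1 dp) of patients
whose group label differs between each pair of stratifications, the
per-tier count of patients on which *all* methods agree, and a per-tier
K-sample log-rank comparison of the per-method tier memberships. Those
membership groups overlap by construction (the same patient sits in several
of them), so the log-rank there is a descriptive statistic, not a test with
its nominal distribution.

The end-to-end driver `run_study()` chains the stages with per-stage seeds
derived from one master seed (`stage_seed`), logs patient counts at every
exclusion, and restricts the analysed cohort to patients with an acceptable
contour under *every* retained method — the concordance matrices require
one common patient set, and the clinical study this replicates likewise
analysed a single common cohort across its four retained methods.

## Numerical and degenerate-input policy

Constant-SUV masks make skewness/kurtosis undefined (NaN with a warning)
and entropy 0; flat regions drive coarseness to its capped sentinel; a
degenerate box (all SUVs equal) fails every segmentation method cleanly;
separation in the Cox fit (monotone partial likelihood) and EM component
collapse (weight below 1e-8) are hard errors/failures rather than silent
large numbers. Ties are broken lexicographically everywhere a voxel must be
chosen (seed voxel, equal cluster means), which is what makes every method
reproducible without randomness.

## Problem sizes and what the tests do (and do not) show

The validation suite runs phantoms at 32x32x26 voxels (boxes of roughly
24^3), cohort simulations at n = 427 and n = 2000 in tabular mode with 100
replicate seeds for the selection properties, feature-oracle checks on 50
random 4x4x4 volumes, and end-to-end imaging studies at 24-60 patients.
These sizes were chosen so the full chain can be exercised routinely; the
published study scale (427 imaged patients) is reached only by the tabular
simulations, because at n around 50 the imaging pipeline's concordance
percentages fluctuate far more than a 427-patient cohort's would.

Passing tests demonstrate internal correctness (formulas match independent
oracles; estimators recover known truth; the pipeline is deterministic and
self-consistent) under the simulator's assumptions. They do not demonstrate
that real oesophageal tumours behave like Gaussian-textured ellipsoids, nor
that any particular clinical failure rate or hazard ratio would be
reproduced on real data — the phantom's fidelity to clinical heterogeneity
is untested and not claimed.
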