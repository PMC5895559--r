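# petrad

Segmentation-dependent radiomic prognostic modelling for FDG PET.

Prognostic models in PET oncology are frequently built from radiomic
features extracted inside the metabolic tumour volume (MTV), but the MTV
itself comes from an automatic segmentation algorithm — and different
algorithms draw different boundaries. `petrad` measures how far that choice
propagates: the same cohort, delineated by several methods, yields
different Cox models, different prognostic scores, and patients who change
risk group purely because the segmentation changed. The package is aimed at
quantitative-imaging researchers who want to study (or stress-test) this
dependence under fully controlled synthetic conditions.

## What it contains

* **Synthetic data** — `phantom_spec()` / `generate_phantom()` build
  ellipsoidal FDG-avid lesions (2.73 × 2.73 × 3.27 mm voxels) with
  within-lesion Gaussian texture, Gaussian PSF blur and noise, plus the
  ground-truth mask; `cohort_spec()` / `generate_cohort()` add clinical
  covariates and overall survival from an exponential
  proportional-hazards process, *h(x) = h₀ exp(βᵀx)*, with known
  coefficients and calibrated uniform censoring.
* **Nine MTV delineation methods** — adaptive iterative thresholding with
  background subtraction (AT, threshold fixed point
  *T = B + w(mean{SUV>T} − B)*), k-means with 2–4 clusters (KM2–KM4),
  fuzzy c-means (FCM2), Gaussian-mixture clustering (GCM3/GCM4), region
  growing with a 5%-growth stopping rule (RG), and a Sobel-gradient
  watershed (WT) — all via `segment_mtv()`, plus an automated
  contour-failure screen, `flag_failed_contour()`.
* **Ten standardised image features** under fixed-bin-size SUV
  discretisation (0.5 SUV bins): volume, SUVmax, energy, skewness,
  kurtosis, entropy, GLCM dissimilarity, GLSZM grey-level non-uniformity
  (Σzᵢ²/N_z) and zone percentage, NGTDM coarseness — `extract_features()`,
  each validated against brute-force oracles.
* **Prognostic modelling** — Cox models with Breslow ties (`fit_cox()`),
  backward elimination on likelihood-ratio removal tests
  (`backward_conditional()`), prognostic scores Σβᵢxᵢ
  (`prognostic_score()`), risk tertiles (`stratify_tertiles()`),
  Kaplan–Meier and log-rank (`kaplan_meier()`, `logrank_test()`).
* **Concordance** — pairwise risk-group change counts (`change_counts()`),
  per-tier all-method concordance (`concordant_counts()`), per-tier
  cross-model log-rank (`cross_model_tier_logrank()`), and the end-to-end
  driver `run_study()`.

## Worked example

```r
library(petrad)

ph  <- generate_phantom(phantom_spec(seed = 42))
box <- truth_bounding_box(ph$truth$mask, margin = 8)
res <- segment_mtv(ph$volume, box, "GCM3")
res
#> <GCM3> ok, 187 voxels, 194 iterations
dice(res$mask, ph$truth$mask)
#> 0.964

extract_features(ph$volume, res$mask, method_name = "GCM3")
#> Feature vector [GCM3]
#>   volume_mm3       4557.37
#>   suv_max          8.77187
#>   energy           7339.93
#>   skewness         0.171124
#>   kurtosis         -1.12741
#>   entropy          3.0896
#>   dissimilarity    2.03562
#>   glnu             6.61111
#>   zone_percentage  0.192513
#>   coarseness       0.0303623
```

The delineated MTV is 4557 mm³ against a ground truth of 4289 mm³
(Dice 0.96); the feature block is what feeds the survival model. Running
the whole study on a 40-patient synthetic cohort:

```r
cfg <- run_config(n_patients = 40, methods = c("AT", "KM2", "GCM3", "WT"),
                  seed = 3)
report <- run_study(cfg)
#> [qc] acceptable fractions: AT 0.97, KM2 0.97, GCM3 1.00, WT 0.97
#> [qc] retained methods: AT, KM2, GCM3, WT
#> [cohort] analysed 39 = generated 40 - excluded 1
report
#> Study report: 39/40 patients analysed, methods AT, KM2, GCM3, WT
#> Overall median OS 22.2 months
#> Patients changing risk group (n = 39), count (%):
#>   KM2       8 (20.5)
#>   GCM3     20 (51.3)   20 (51.3)
#>   WT        7 (17.9)   13 (33.3)   19 (48.7)
#>          AT          KM2         GCM3

report$models$WT
#> Cox model (breslow ties): 39 subjects, 23 events, logLik -56.316
#>                 estimate         p       HR   95% CI
#>   treatment       -2.689  1.72e-05    0.068 0.020-0.231
#>   glnu            -0.310   0.00503    0.733 0.591-0.911
```

Each cell of the change matrix counts patients assigned different risk
tertiles by the two methods' models: here up to 51% of this small cohort
changes group depending on the delineation algorithm, even though every
model was built from identical clinical data. `write_report(report, dir)`
emits the cohort, feature, model, stratification and concordance tables as
CSV/JSON.

A thin command-line wrapper is installed at
`inst/scripts/run_study.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts/run_study.R", package="petrad"))')" \
    --config run.json --out results/
```

## Scope notes

The simulator is a testing instrument, not a scanner model: no sinograms,
scatter or reconstruction physics, one lesion per volume, Gaussian texture.
Shape features beyond volume, fixed-bin-number discretisation as a primary
path, and machine-learned/consensus segmentation are deliberately out of
scope. See the vignette
(`vignettes/segmentation-dependent-prognosis.Rmd`) for the full methods
account and design rationale.
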