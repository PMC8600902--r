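# tacsquant

Computer-assisted quantification of collagen organisation in
second-harmonic-generation (SHG) microscopy and construction of
collagen-based prognostic scores for survival analysis.

## The problem

Collagen fibers in the tumor microenvironment reorganise as a tumor grows
and invades. At the macroscale these arrangements are described by the
eight tumor-associated collagen signatures (TACS1–8) — wrapping, parallel,
radiating, reticular, aligned, chaotic, dense and sparse patterns at the
tumor boundary — which are read visually from multiphoton images and are
strong prognostic markers in invasive breast cancer. `tacsquant`
implements the corresponding *microscopic* analysis: it converts each
150 μm × 150 μm SHG region of interest (ROI) into 142 quantitative
TACS-corresponding microscopic features (TCMFs) and turns them into
prognostic scores for disease-free survival (DFS).

The 142-feature panel is

* **8 morphological features** from a traced fiber network: collagen area
  fraction, fiber number, mean length, mean width, straightness
  (chord/arc), crosslink density, crosslink spacing, and orientation
  concentration (axial circular statistics);
* **6 first-order histogram features**: mean, variance, skewness,
  kurtosis, energy `Σp²`, entropy `−Σp log₂p`;
* **80 gray-level co-occurrence (GLCM) features**: contrast, correlation,
  energy and homogeneity of the symmetric normalized co-occurrence matrix
  at 5 pixel displacements × 4 directions;
* **48 Gabor features**: mean and standard deviation of the magnitude
  response of a complex Gabor bank at 4 frequencies × 6 orientations.

Per patient, ROI vectors are averaged and Z-scored with training-cohort
statistics. Scores are then built the way the prognostic literature does:

* **TCMF-score** — LASSO-penalized Cox regression over the 142 features;
  the score is `Σ βᵢ xᵢ` over the selected features,
* **TACS-score** — ridge-penalized Cox over the eight TACS indicators,
* **CLI-score** — unpenalized Cox over encoded clinical covariates,
* **combined scores** — a multivariate Cox fit over component scores
  provides the relative weights.

Evaluation covers IPCW cumulative/dynamic ROC at a survival horizon with
Youden-optimal cutoffs, Kaplan–Meier risk stratification with log-rank
tests and hazard ratios, time-dependent AUC and event-density-weighted
iAUC, Harrell's C-index, nomograms with Breslow-baseline survival maps and
bootstrap calibration, and per-subgroup HR/AUC reports.

A synthetic-data module generates SHG-like fiber images with pixel-level
ground truth (fiber centerlines, widths, orientations, curvature,
crosslinks — including presets for the eight TACS archetypes) and survival
cohorts from a Weibull proportional-hazards model with a known linear
predictor, so the entire pipeline is testable without patient data.

## Worked example

```r
library(tacsquant)

# a reticular (TACS4) synthetic ROI, and its 142-feature vector
sim   <- simulate_tacs_archetype(4, seed = 1)
print(sim$image)
#> <shg_image 'sim_seed1'> 256 x 256 px, 0.5859 um/px (150.0 x 150.0 um), 8-bit
#>   intensity range [0, 255]
feats <- extract_tcmf(sim$image)
round(feats[1:8], 3)
#>             morph_area_fraction               morph_fiber_count
#>                           0.164                         103.000
#>               morph_mean_length                morph_mean_width
#>                          14.296                           1.912
#>              morph_straightness         morph_crosslink_density
#>                           0.963                           3.197
#>           morph_crosslink_space morph_orientation_concentration
#>                           7.125                           0.112

# a simulated cohort with two prognostic features among 142, and a
# LASSO-Cox score fitted on the training cohort
tab   <- simulate_cohort(cohort_sim_params(
  n_patients = 600, beta = c(f1 = 1, f2 = -0.9), n_noise_features = 140,
  censor_target = 0.25, seed = 2))
tr    <- tab[tab$cohort == "training", ]
X     <- as.matrix(tr[, c("f1", "f2", paste0("noise_", 1:140))])
model <- fit_lasso_cox(X, tr$dfs_months, tr$event, seed = 1)
print(model)
#> <score_model kind='tcmf'> 5 feature(s)
#>   f1                               +0.67322
#>   f2                               -0.66377
#>   noise_48                         -0.00469
#>   noise_96                         +0.01925
#>   noise_126                        -0.01820

# held-out evaluation: 5-year ROC and concordance
val <- tab[tab$cohort != "training", ]
s   <- score(model, val)
roc_at_horizon(s, val$dfs_months, val$event, horizon = 60, seed = 1)
#> AUC at 60 months: 0.830 [0.782-0.874]
#> Youden cutoff -0.0921: sens 0.825, spec 0.673, acc 0.745
ci <- concordance_index(s, val$dfs_months, val$event)
#> C-index 0.775 [0.745-0.805]
```

The planted features `f1` and `f2` dominate the selected model with the
correct signs; the held-out AUC/C-index quantify how much survival signal
the score carries. `vignettes/tacsquant-methods.Rmd` documents the models,
conventions and parameter defaults in detail.

A thin command-line dispatcher over the same functions is installed at
`inst/cli/tacsquant.R` with subcommands `simulate-image`,
`simulate-cohort`, `extract`, `fit` and `evaluate`, each taking
`--config`, `--seed` and `--out`.

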