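---
title: "Collagen quantification and prognostic scoring: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Collagen quantification and prognostic scoring: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, conventions and design choices behind
`tacsquant`: how an SHG region of interest becomes a 142-entry feature
vector, how feature vectors become prognostic scores, how scores are
evaluated, and what the synthetic-data generators do and do not emulate.

## Conventions

* Pixel coordinates are 0-based, row-major, origin at the top-left.
  Orientations are measured counter-clockwise from the +x (column) axis in
  degrees on [0°, 180°); because fibers are axial (a fiber at 10° is the
  same fiber at 190°), all circular statistics use the doubled-angle
  convention.
* Time is in months throughout; the "5-year" horizon is 60 months.
* Images carry intensities on their native integer scale (0–255 or
  0–65535) with the acquisition bit depth stored alongside; the default
  pixel size (150/512 ≈ 0.293 μm) maps a 512×512 ROI onto the
  150 μm × 150 μm field of view, and is overridable everywhere.

## From ROI to feature vector

**Segmentation.** Collagen is separated from background by light Gaussian
smoothing (σ = 1 px) followed by a global Otsu threshold
(between-class-variance criterion). A constant positive image has no
definable threshold and raises an explicit degenerate-input error; an
all-zero image yields an empty mask. Thresholding is the simplest
defensible default for high-contrast SHG; the method slot exists so a
different operator can be swapped in without touching callers.

**Fiber tracing.** The mask is thinned to a 1-px skeleton (Zhang–Suen).
The skeleton pixel graph uses minimal 8-connectivity: a diagonal adjacency
is kept only when neither flanking orthogonal pixel is present, which
prevents staircase corners from masquerading as branch points. Spurs
shorter than 3 μm are pruned iteratively. Remaining pixels of degree ≥ 3
are branch points; adjacent branch pixels are merged into one crosslink at
their centroid, so thick junctions are not double-counted. Skeleton
segments between endpoints/crosslinks become fibers; two segments meeting
at a crosslink are joined into one fiber when their incoming tangents
(estimated over the last 5 px) differ by less than 20° — the smooth
continuation rule, which makes two crossing straight fibers come out as
two fibers and one crosslink rather than four stubs. Fibers shorter than
5 μm are discarded. The spur, length and angle thresholds are
configuration values; nothing in the morphology depends on them being
exactly these numbers, but they are the package's fixed defaults.

Traced polylines are smoothed with a 5-point moving average (endpoints
pinned) before lengths are measured: raw 8-connected chain lengths
overestimate the true arc length of oblique curves by up to ~15%, and the
smoothed length restores the chord/arc straightness of a digitized
semicircle to within 0.01 of its closed form 2/π.

**Morphological features (8).** Area fraction (mask/total pixels), fiber
count, mean arc length (μm), mean width (μm; twice the Euclidean distance
transform sampled along the skeleton, minus one pixel — the transform of a
w-px stroke reads (w+1)/2 at its centerline), mean straightness
(endpoint chord / arc length), crosslink density (crosslinks per 100 μm²
of collagen), crosslink spacing (mean skeleton path length between
adjacent distinct crosslinks), and orientation concentration (length of
the mean resultant of doubled fiber chord angles: 1 = perfectly aligned,
0 = isotropic). An empty network reports 0 for every feature — a sentinel
convention chosen so downstream Z-scoring never propagates non-finite
values; patients whose every ROI is empty should be excluded upstream, as
is done for patients whose collagen is too sparse to quantify.

**Histogram features (6).** Computed from the normalized 256-bin histogram
over the bit-depth range. For 8-bit input each bin is one integer
intensity, so histogram moments equal exact pixel moments. Kurtosis is
uncorrected (normal = 3); a zero-variance image reports skewness and
kurtosis 0 by convention, making energy = 1 equivalent to entropy = 0.

**GLCM features (80).** Intensities are quantized to 16 uniform levels
over the observed min–max range (which also makes the features invariant
to global intensity shifts). For each displacement d ∈ {1..5} and
direction θ ∈ {0°, 45°, 90°, 135°} the co-occurrence matrix is accumulated
symmetrically (θ and θ+180° are equivalent for fibers) and normalized;
contrast, correlation, energy and homogeneity are emitted per (d, θ),
named `glcm_<stat>_d<d>_a<θ>`. Correlation of a single-level image is 0 by
the zero-variance convention.

**Gabor features (48).** A complex Gabor bank with one-octave bandwidth,
frequencies {0.05, 0.1, 0.2, 0.4} cycles/px and orientations 0°–150° in
30° steps; per filter the mean and standard deviation of the magnitude
response are kept. The real part is DC-corrected so constant images
respond at numerical zero. Kernels are truncated at 3σ and capped at the
image size; FFT convolution with replicate boundaries.

**Assembly.** The ordered registry is 8 morphological + 6 histogram +
80 GLCM + 48 Gabor = 142 named features. The per-family texture counts
follow the default displacement/angle/frequency sets and are
configuration-driven: changing those sets re-derives a consistent registry
without code changes. Texture is computed on the raw ROI by default (the
collagen-masked variant is a config toggle).

**Aggregation and normalization.** Patient vectors are the uniform
(unweighted) mean over the patient's ROIs — aggregation happens first,
then all features are Z-scored with mean/sd estimated on the training
cohort only (sample sd, n−1). Validation cohorts are transformed with the
stored training parameters, never refit, so distribution shifts remain
visible. Zero-variance training features are dropped with a warning.

## Prognostic scores

All Cox partial likelihoods use the Efron tie approximation.

* **TCMF-score**: L1-penalized Cox over the normalized features
  (`glmnet`), penalty chosen by 10-fold cross-validated partial likelihood
  with event-stratified, seeded folds; the 1-SE rule is the default
  (configurable to the CV minimum). Features are not re-standardized
  inside the penalized fit — they are already Z-scored upstream, and
  double standardization would silently reweight the penalty. The score is
  the linear combination of selected features weighted by their LASSO
  coefficients; an all-zero fit returns an explicit empty model whose
  score is identically 0.
* **TACS-score**: L2-penalized Cox over the eight TACS indicator columns,
  all coefficients retained, penalty by cross-validated partial
  likelihood.
* **CLI-score**: unpenalized Cox over clinical covariates expanded to
  treatment contrasts against fixed reference levels (age ≤ 50, Luminal A,
  T1, N0, stage I, G1, receptor-negative, therapy "No"). The level maps
  are stored in the model so new tables are encoded identically; unseen
  category levels are an error, not a silent reference assignment.
  Constant encoded columns are dropped with a warning (a cohort with
  identical covariates scores constant 0).
* **Combined scores**: a multivariate Cox fit over the component score
  columns of the training cohort; the fitted coefficients are the
  relative weights and the combined score is their linear combination.
  Near-collinear components trigger a condition-number warning.

## Evaluation

* **Horizon ROC** uses the cumulative/dynamic definition with
  inverse-probability-of-censoring weights: cases are events by the
  horizon weighted by 1/G(T⁻), controls are patients past the horizon
  weighted by 1/G(horizon), with G the Kaplan–Meier estimate of the
  censoring distribution. The incident/dynamic variant is deliberately not
  offered. AUC confidence intervals are a seeded patient-level percentile
  bootstrap (default 1000 replicates). The risk cutoff maximizes the
  Youden index on the training cohort (ties resolved toward the lower
  cutoff) and is frozen for validation cohorts.
* **Time-dependent AUC / iAUC**: AUC(t) over a user grid with the same
  estimator; iAUC integrates AUC(t) with weights proportional to the
  number of observed events in each grid interval (a Riemann sum against
  the event-time density). Grid points without comparable pairs are
  dropped with a warning.
* **Risk stratification**: product-limit curves with Greenwood variance,
  the log-rank test, and a between-group hazard ratio from a univariate
  Cox fit on the group indicator. A cohort without events is an explicit
  error, not a silent NA.
* **Cox reporting**: Wald confidence intervals and likelihood-ratio
  p-values; in multivariate mode each covariate's p-value is the LRT of
  dropping it from the joint model. Fewer than five events per covariate
  triggers a warning. No multiple-testing correction is applied; reported
  p-values are raw.
* **C-index**: Harrell's estimator via `survival::concordance`
  (higher score = higher risk; score ties count ½), with a normal CI from
  its standard error. The exhaustive O(n²) pair count lives in the test
  suite as the independent oracle.
* **Nomogram**: per-covariate points proportional to |β × range| with the
  widest covariate spanning 100 points; total points map to survival at
  12/36/60 months through the Breslow baseline; discrimination by C-index
  and calibration by bootstrap-resampled predicted-vs-KM-observed survival
  in four risk-quantile bins (200 replicates).
* **Score→DFS curves**: S(60 | s) = S₀(60)^exp(βs) from a univariate Cox
  fit with the Breslow baseline, evaluated over a score grid.

## The synthetic-data generators

**Images.** Fibers are circular arcs: the curvature parameter is the total
turning angle φ (radians), so ground-truth straightness is
sin(φ/2)/(φ/2) in closed form (φ = π gives the semicircle, 2/π). Fiber
orientations are drawn from a von Mises distribution on the doubled angle
and folded to [0°, 180°) — the axial analogue of a normal distribution;
κ = 0 is isotropic. Crosslinks are realized by branching new polylines off
a parent fiber at a uniform position, matching the skeleton branch-point
definition used by the extractor. Strokes are rendered with anti-aliased
coverage (distance to the centerline against half the stroke width), shot
noise (Poisson) is optional, Gaussian read noise additive, and the result
is rounded and clipped to the bit depth, so identical parameters and seed
give bitwise identical images. The eight TACS archetype presets differ
only in interpretable parameters: curvature (TACS1), mean orientation
relative to a declared boundary axis (TACS2 parallel / TACS3
perpendicular), crosslink rate (TACS4), orientation concentration (TACS5
high κ / TACS6 κ = 0) and fiber count (TACS7 dense / TACS8 sparse).

What the simulator does *not* emulate: background autofluorescence and
non-collagen structures, intensity attenuation with depth, curvelet-scale
texture of real collagen bundles, wavy (non-circular) fiber paths, and
tumor-cell shadows. Passing tests therefore demonstrate correctness of the
pipeline's algorithms under controlled geometry, not clinical performance
on real tissue.

**Cohorts.** Event times follow a Weibull proportional-hazards model
S(t|x) = exp(−(t/λ)^k · e^η) with η = β·x over standardized latent
features (and/or Bernoulli TACS indicators), shape k = 1.5 and scale
λ = 90 months by default — a median event time near the ~70-month DFS
scale of the motivating cohorts. Two patients whose linear predictors
differ by Δ have generating hazard ratio exactly exp(Δ). Censoring is an
administrative horizon (150 months by default) plus an independent
exponential time whose rate is solved by root-finding from the drawn event
times so the expected censored fraction hits the target; when
administrative censoring alone exceeds the target the rate is 0 and a
warning is raised. The generating linear predictor is returned per patient
(`true_eta`) for oracle checks.

## Numerical choices and degenerate inputs

* Thinning artefacts: the minimal-8-connectivity graph and junction
  merging are what keep a digitized cross at one crosslink and a digitized
  circle at zero.
* Tangent estimation over 5 px trades angular resolution (~11° at that
  scale) against noise; together with the 20° continuation threshold it
  joins smooth continuations and refuses right-angle ones.
* Empty-network sentinels are 0, not NaN (see morphology above).
* Quantization to 16 GLCM levels over min–max is standard practice; the
  checkerboard identity (contrast 1) requires quantization at the
  image's own level count, which is why `levels` is exposed.
* Problem sizes in the test suite are chosen to keep the default run fast
  on one CPU: the end-to-end image→score→evaluation recovery runs 400
  patients with one 96-px ROI each; penalized-recovery studies use 50
  replicates of n = 500 × 142 features; estimator-calibration checks use
  n = 1000–2000.

## Known limitations

* Segmentation is a global threshold; heavily vignetted or bimodal
  backgrounds would need a local method.
* Fiber width from the distance transform reports the mean stroke width;
  it does not model overlapping bundles.
* The TACS archetype presets are parameter presets at ROI scale, not
  spatial models of a tumor boundary; no boundary detection is attempted
  (TACS labels are inputs, not outputs).
* The published per-patient supplementary score tables can be ingested
  through the cohort reader (extra score columns are tolerated and
  re-evaluated deterministically), but the package does not ship them.
* No competing-risks or landmark analyses; the evaluation machinery is
  cause-agnostic DFS only.
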