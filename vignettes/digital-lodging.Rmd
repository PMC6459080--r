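---
title: "Digital lodging from differential elevation models: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Digital lodging from differential elevation models: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models behind `lodgepipe`, the tunable
parameters that matter, the design choices made where the design was
genuinely open, and what the synthetic-data tests do and do not establish
about real UAV data.

## 1. The differential-DEM model of lodging

Two georeferenced elevation rasters are taken per season: pre-lodging and
post-lodging. The differential DEM is the per-pixel difference
`pre − post`, so positive values are canopy drop. Pixels are attributed
to plots by the **pixel-center-in-polygon** rule (strict interior):
deterministic, order-independent, and cheap. Area-weighted membership was
rejected for simplicity — at the 1.5–3.5 cm ground resolutions typical of
these flights a plot contains thousands of pixels and boundary pixels are
a negligible fraction. No boundary buffer is applied by default; plots are
extracted exactly to their polygon (`extract_plot_pixels()` takes any
polygon, so a caller can shrink polygons beforehand if alley
contamination is a concern).

Two plot-level scores are computed:

- **DLmean**: the arithmetic mean of the plot's differential pixels. Under
  the generative model below its expectation is `λ₂·μ₂` minus any uniform
  between-flight growth.
- **DLmix**: from a two-component normal mixture with the *first
  component mean anchored at zero*:
  `d ~ (1 − λ₂)·N(0, σ₁²) + λ₂·N(μ₂, σ₂²)`, and `DLmix = λ₂·μ₂`.
  The zero anchor encodes the physical prior that standing canopy does
  not change elevation between flights; `λ₂` estimates the lodged area
  fraction and `μ₂` the mean drop of lodged pixels.

### EM details

The fit is a standard EM with the anchor constraint: E-step
responsibilities for the lodged component; M-step `λ₂ = mean(γ)`,
`μ₂, σ₂²` = responsibility-weighted mean/variance, and
`σ₁²` = the `(1 − γ)`-weighted *second moment about zero* (not about a
fitted mean — this is where the anchor enters). Numerical choices:

- convergence on `|Δ log-likelihood| < 1e-8`, at most 500 iterations;
- both variances free (only the first mean is constrained), floored at
  `1e-6 m²`; touching the floor flags the fit degenerate;
- deterministic initialisation: `λ₂ = 0.5`; `μ₂` = mean of pixels above
  the 75th percentile; `σ₁` = 1.4826 × MAD (about zero) of pixels below
  the median; `σ₂` = sd of the upper-quartile pixels. No random restarts:
  with thousands of pixels and well-separated components the likelihood
  surface is benign, and determinism is worth more than insurance against
  a pathological local optimum;
- fewer than 50 pixels: no mixture is fitted; the plot falls back to
  DLmean-based reporting with a degenerate flag;
- a converged *negative* `μ₂` means the "lodged" component rose — growth,
  not lodging — so DLmix is clamped to 0 and flagged. This keeps the
  index non-negative like the visual scores it mirrors.

The EM log-likelihood trace is stored and asserted non-decreasing in the
tests (degenerate variance clamps are the only event that could break
monotonicity, and they are flagged).

## 2. The synthetic field generator

The generator reproduces the statistical structure the analysis assumes,
with defaults matching the emulated study design: 11 trials, each with 53
related entries plus 7 checks shared across trials, two complete
replicates of 120 plots per trial split into six sub-blocks of ten,
1.3 m × 3.8 m plots with 52/80 cm gaps — 1,320 plots and 590 unique
lines. Key modelling choices:

- **Genotypes.** Inbred ±1 calls at base MAFs uniform on
  `maf_range = (0.05, 0.5)`; each trial draws its own allele frequencies
  from a Balding–Nichols Beta around the base frequency at `fst = 0.05`.
  This makes within-trial relatedness exceed between-trial relatedness,
  which is exactly what makes leave-one-trial-out cross-validation harder
  than random folds (the design rationale for trial-wise folds).
- **Liability.** Entry liability is an additive polygenic value over
  `n_qtl = 100` markers (optionally one major alien-segment-like locus),
  standardised to unit variance. Plot liability adds replicate and
  sub-block effects (variance 0.1 each) and a residual whose variance is
  set to `r(1 − h²)/h²`, so `h2_lodging` is the *entry-mean* heritability
  at the configured replicate number. The entry-mean interpretation was
  chosen because it is the scale on which repeatability is reported and
  recovered by the REML machinery; a plot-level interpretation would
  inflate realized entry-mean H² (0.6 plot-level implies 0.75 entry-mean
  at r = 2).
- **Liability → lodging maps.** Lodged fraction is logistic in liability
  (slope 1, center 0 — both configurable); any monotone map preserves the
  validation properties. Severity angle is clipped-linear
  (`45 + 20·liability`, clamped to [0, 90]°), and the mean drop of lodged
  pixels is `canopy · (1 − cos angle)` — the vertical loss of a stem
  pivoted at the ground.
- **Rasters.** Ground at zero, per-plot canopy height `N(1.0, 0.05²)` m,
  i.i.d. pixel noise of 3 cm sd on each flight (the coarser of the two
  reported DEM resolutions motivates the default). Lodged pixels form one
  *contiguous* patch filled from a seeded random end of the plot —
  lodging is spatially clustered in real fields, and a contiguous patch
  stresses zonal extraction harder than salt-and-pepper noise would.
- **Between-flight growth.** Whether canopy growth over the roughly
  two-week flight gap biases differential DEMs is an open question in the
  emulated protocol; the generator exposes `growth_offset_m` (applied to
  all plot pixels, so `E[differential] = λ·drop − offset`) to probe it,
  and defaults to 0. A nonzero offset violates the zero-anchor assumption
  of DLmix by design — that is the point of the probe.
- **Visual scores.** `LOI = 100·fraction + N(0, 5)`, rounded to the
  nearest 5 (scorers work in 5% steps) and clipped to [0, 100];
  `LOS = angle/9 + N(0, 0.5)` rounded and clipped to [0, 10];
  `LI = LOI × LOS`.
- **Diagnostic tags.** Carriers of the alien segment draw alien-specific
  tag counts `Binomial(depth, 0.95)`, non-carriers `Binomial(depth,
  0.02)`; the caller thresholds the alien fraction at `tau = 0.5` with a
  minimum depth of 10 (the original caller's threshold is unpublished,
  so it is exposed as a parameter).

**What the generator does *not* emulate** — and hence what passing tests
do not show about real data: photogrammetric reconstruction artifacts
(doming, stitching seams, GCP misregistration), spatially correlated
elevation noise, terrain relief, partial/leaning lodging gradients within
a patch, phenology differences among entries, and real linkage
disequilibrium structure (markers are independent given the trial).
Results on synthetic fields bound what the algorithms can do when their
assumptions hold; they do not certify the photogrammetry upstream.

## 3. Phenotypic mixed models

Per trial and trait, variance components come from the model
`y = μ + G + M + e` with random genotype `G`, random sub-block nested in
replicate `M`, and residual `e`; entry-mean heritability is
`H² = σ²_G/(σ²_G + σ²_e/r)`. Heritability is reported per trial and as
the mean over trials (trials are separate incomplete-block randomisations
of different entry sets, so pooling the variance components across trials
has no clean interpretation).

REML implementation: one-way balanced designs use the exact ANOVA
identity (`σ²_e = MSE`, `σ²_G = max(0, (MSB − MSE)/r)`), which *is* the
REML solution there and stays exact on the boundary `σ²_e = 0` where
general-purpose optimisers deliver approximate (and occasionally badly
wrong) boundary estimates; every other design is fitted by `lme4` REML.
Negative components are clamped at zero (the usual choice; the emulated
analysis does not state its convention). Genotype BLUEs use the
across-trial model with fixed genotype and random trial, replicate-in-
trial and sub-block effects; with all random variances at zero the GLS
reduces to OLS, which the tests assert. Two-year adjusted means are plain
two-way fixed-effects least squares, reported at the average year.

**Genetic correlations.** `r_g = cov_g/√(var_g(x)·var_g(y))` with genetic
(co)variances structured by the kinship matrix. Rather than a joint
bivariate sampler, the package computes the three univariate REML fits
for `x`, `y` and `x + y` (each exact, by spectral decomposition of K) and
uses the polarisation identity `cov_g = (var_g(x+y) − var_g(x) −
var_g(y))/2`. Each univariate fit maximises its restricted likelihood to
`1e-10` in the variance ratio; REML's exact scale equivariance makes
self-correlation 1 and negation −1 exactly, and parameter-recovery tests
confirm calibration at intermediate values. Estimates are clipped to
[−1, 1]; near-zero genetic variance in either trait flags the result as
boundary/undefined instead of reporting a ratio of noise.

## 4. GWAS

Single-marker tests in the mixed model `y = Xβ + Zu + Sτ + e` with
`u ~ N(0, σ²_u K)`, VanRaden kinship, and fixed covariates = intercept +
principal components of K (+ any user covariates such as year). The
number of PCs is not dictated by the emulated analysis; the default is 3,
configurable, and with K in the model the tests are calibrated across a
range of sensible choices (the permutation-null test asserts this at the
default). Variance components are estimated once under the no-marker
null and reused for all markers (P3D/EMMAX); `exact = TRUE` re-estimates
per marker, and the two agree closely on small instances (tested).
q-values use Storey's procedure with `π₀` estimated at the single point
`λ = 0.5` — robust at the ~10⁴-marker scale this targets — floored at
`1/m`.

Marker QC follows the stated filters as strict inequalities (missing
< 40%, heterozygosity < 10% per marker; then lines with > 50% missing
dropped). LD-aware imputation is out of scope; heterozygous calls are set
missing and modes imputed per marker (ties break deterministically to the
−1 allele). None of the package's claims depend on imputation quality.

## 5. Whole-genome prediction

Three models with one prediction interface:

- **RR-BLUP**: ridge of all marker effects, shrinkage ratio by REML via
  the spectral decomposition of `W Wᵀ`; identical (≤ 1e-8, tested) to
  kinship-form GBLUP.
- **BayesCπ**: Gibbs sampler (C++) with per-marker inclusion indicators,
  a common effect variance with scaled-inverse-χ² prior (df 5, scales
  split by a prior variance-explained guess R² = 0.5), uniform prior on
  the inclusion proportion. Reported `π` is the proportion of *zero*
  effects. Chain defaults are 10,000 iterations / 3,000 burn-in /
  thinning 3; `preset = "reduced"` (2,000/500/2) is a clearly-labelled
  short chain used in the test suite.
- **RKHS**: Gaussian kernel `exp(−h·D²/median(D²))` on marker distances
  (bandwidth scale-free via the median; default `h = 1`), fitted by Gibbs
  in the kernel eigenbasis with the same chain settings; a REML
  kernel-ridge variant is available behind `method = "reml"`.

**Cross-validation.** One fold per trial (leave-one-trial-out): trials
group related lines, so this split keeps close relatives out of the
train/test pair. Checks appear in every trial; they stay in training and
are excluded from test-set correlations — scoring an entry present in
training would leak. The fold-aggregation of predictive ability is not
dictated by the emulated analysis; the default is the **mean of
within-fold correlations** (pooled predictions mix fold-specific
intercept shifts into the correlation), with the pooled alternative
behind a flag. Prediction accuracy is `r_pa = r_pv/√H²`; the H² used is
the whole-dataset REML H² for the trait (one H² per trait-year is how
such tables are printed), computed on the same data slice as the CV.

## 6. Problem sizes and runtime choices

The test suite and acceptance script run at the scales the methods are
specified at where that is cheap (the full 1,320-plot default field, EM
recovery on 20,000 pixels, heritability recovery over 100 simulations of
500 entries × 2 reps, GWAS calibration over 40 permutation seeds and 50
power replicates at n = 600 × 1,000 markers) and at reduced-but-adequate
scales for the MCMC samplers (reduced chain preset; model-comparability
checks on ~360 lines × 400 markers), chosen so the whole suite completes
in a few minutes of CPU. Raster I/O uses the plain-text ESRI ASCII grid
format (`.asc`), and plot polygons GeoJSON, so artifacts remain
inspectable and portable.

## 7. Known limitations

- The DEM pipeline starts from elevation rasters; photogrammetric
  reconstruction is upstream and out of scope.
- The zero-anchored mixture assumes no systematic elevation change of
  standing canopy between flights; uniform growth biases both DLmean and
  DLmix by the same offset (probe with `growth_offset_m`).
- `lme4`-based fits inherit its boundary behaviour for the nested
  sub-block model (the one-way path is exact).
- The bivariate genetic-correlation estimator assumes a shared kinship
  and homogeneous residual structure across the two traits.
- BayesCπ posterior summaries at the reduced preset are for fast checks,
  not publication-grade inference; use the full chain for real analyses.
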