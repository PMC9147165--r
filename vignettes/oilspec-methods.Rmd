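---
title: "Models and design choices in oilspec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in oilspec}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(oilspec)
```

`oilspec` builds and screens multivariate calibrations that predict
vegetable-oil quality — fatty-acid composition and pharmacopoeial indices —
from FT-IR absorbance spectra. This vignette explains the model behind
each stage, the parameters that matter and why their defaults are what
they are, what the synthetic data generator does and does not emulate,
and the numerical conventions the implementation commits to.

## The calibration model

The scientific premise is Beer–Lambert mixing: an oil's absorbance
spectrum is approximately the concentration-weighted sum of the spectra
of its constituents. A quality value that is a (near-)linear function of
composition — a fatty-acid percentage, or the iodine value, which counts
double bonds — is therefore a linear function of the spectrum, and a
linear multivariate calibration is appropriate.

With ~30 calibration samples and thousands of wavenumbers, ordinary
least squares is hopelessly underdetermined; partial least squares
regression (PLS1) resolves this by extracting a small number of latent
factors that maximize covariance with the response. We implement the
classical NIPALS sequence on column-mean-centred features `X` and centred
response `y`; per factor:

```
w = X'y / ||X'y||      # weight (covariance direction)
t = X w                # scores
c = t'y / t't          # response loading
p = X't / t't          # feature loadings
X <- X - t p' ;  y <- y - c t
```

and the regression vector is `b = W (P'W)^-1 c`, so predictions are
`(X - x_mean) b + y_mean`. Features are centred but not autoscaled:
absorbance channels share physical units, and variance-scaling would
inflate noise channels.

The factor count is the one free hyperparameter. It is chosen by
leave-one-sample-out cross-validation over `k = 1..20`: each calibration
*sample* — all of its replicate spectra together — is held out, the model
refit, and the held-out spectra predicted; `best_k` minimizes RMSECV,
with ties going to the smaller k. Holding out single spectra instead
would let the model see the held-out sample through its sister
replicates and systematically understate the error; the package
therefore groups replicates in all modes. The global RMSECV minimizer is
used rather than a one-standard-error rule, since the aim is the most
appropriate factor count, not the most conservative one. Extraction also
stops early when `||X'y|| < 1e-12` (no predictive covariance left); the
realised factor count is recorded, and a response orthogonal to the
features yields the zero regression vector.

Model quality is reported as R²c and R²v — the coefficient of
determination `1 - SSres/SStot`, which on an independent validation set
can be negative when the model predicts worse than the validation mean —
plus RMSEC, RMSECV and RMSEP. RMSEV and RMSEP are the same quantity
(validation-set root-mean-square error) under two historical names; the
package reports it once, as `rmsep`.

### A note on the cross-validation implementation

The CV loop runs on an orthonormal row-space reduction of the feature
matrix: `Z` with `Z Z' = X X'` (symmetric eigendecomposition), so
`X = Z V'` for an orthonormal `V`. Every quantity in NIPALS PLS1 —
centring, weights, scores, predictions — depends on `X` only through
inner products of its rows, so predictions computed from row-subsets of
`Z` are identical to those from `X`, while each fold costs O(n²) instead
of O(n·q). A dedicated test verifies the equivalence against explicit
fold-by-fold fits in the original space.

## Preprocessing variants

Sixteen variants are screened, five base transforms × three derivative
orders plus the random control:

- **NOR** — scale each spectrum to unit Euclidean norm. ("Normalization"
  is ambiguous in chemometrics; unit-norm was chosen over unit-area as
  the default because it is the common choice for absorbance vectors, and
  the row primitive is exposed so either can be composed by hand.)
- **SNV** — centre each spectrum and scale to unit standard deviation
  (n−1 denominator, the conventional definition). SNV removes additive
  offsets and multiplicative scatter exactly.
- **WA / WD** — single-level orthonormal Haar transform; approximation
  coefficients `(x[2i] + x[2i+1])/√2` halve the variable count while
  preserving energy, detail coefficients `(x[2i] − x[2i+1])/√2` carry
  local contrast. Odd-length rows are extended by repeating the last
  point. The coefficients' effective wavenumbers are the pair midpoints
  on the continued uniform grid, which keeps the axis uniform so
  derivatives of wavelet features remain defined. A single level was
  chosen (multi-level compression discards too much of a ~850-point
  spectrum at 8 cm⁻¹).
- **D1 / D2** — plain first differences on the uniform grid, applied
  once or twice, with midpoint axes. No Savitzky–Golay smoothing is
  applied by default: derivatives here are the minimal definition, and
  smoothing would be a second, confounded preprocessing choice.
- **RANDOM** — the feature matrix is replaced by seeded standard-normal
  noise of the same shape. This is the null control for the whole
  screening exercise: with many variables and an exhaustive grid, some
  models *will* fit the calibration set perfectly by chance, and the
  random control quantifies exactly how far that chance fitting
  generalizes (it should not).

Composition order is fixed as base-then-derivative (the first derivative
of normalized spectra, not the normalization of a derivative).

## Variable selection

All three strategies reduce the feature set before PLS — STD (largest
across-sample standard deviation), CORR (largest |Pearson r| with the
response) and CHEM (closed wavenumber windows covering the fingerprint
region, the C=O stretch, the C–H/olefinic stretches and the O–H band).
Two conventions matter:

- STD and CORR statistics are computed on **calibration rows only**.
  Using all samples would leak validation information into the model via
  CORR; the scope is exposed but defaults to calibration.
- The retained count is `max(1, round(0.4 q))` with
  round-half-away-from-zero (base R's banker's rounding would make tie
  counts depend on parity), and score ties break toward the lower
  wavenumber for reproducibility.

CHEM is response-independent and is applied to the *effective* axis, so
derivative and wavelet features are selected by the wavenumbers they
actually represent.

## The model grid

`enumerate_grid()` crosses 2 techniques × 3 resolutions × 2 replicate
modes × 3 selections × 16 preprocessing variants × 13 responses = 7488
configurations, each with a deterministic derived seed (used only by the
RANDOM control). `run_model()` executes one cell; degenerate cells
(empty selection, constant response, non-finite metrics) become
`status = "degenerate"` records with `NA` metrics and are excluded from
summary denominators rather than crashing the run. Records are
independent of execution order, and `run_grid()` can resume from a
partial CSV.

Report tables follow three conventions worth stating: R² thresholds are
inclusive (≥); the per-design-factor table excludes RANDOM records (it
compares acquisition choices on spectral data); and best models rank by
descending R²v, then ascending RMSEP, then ascending factor count.

## The synthetic data generator

The generator exists because the reference spectra for this kind of
study are rarely published; it produces data with the statistical
structure the analysis assumes, so that every stage — and the pipeline's
ability to distinguish predictable from unpredictable responses — is
testable end to end.

Design shape: 17 oil types with 1–4 samples each (37 samples in the
default design, 29 calibration / 8 validation after the oil-type-aware
split), 3 replicate spectra per sample, ATR and transmission blocks at
2/4/8 cm⁻¹ with point spacing of half the nominal resolution.

Each of eight components (six fatty acyls, an unsaponifiable fraction, a
hydroperoxide oxidation marker) has a Gaussian band library; band
positions follow the chemistry the CHEM windows target (ester C=O
~1745 cm⁻¹, C–H stretches 2850–2930, olefinic =C–H just above 3000 with
amplitude growing with double-bond count, the trans-isomer band near
966 cm⁻¹, broad O–H features for the non-acyl components). A sample's
noiseless spectrum is the composition-weighted sum of component spectra;
replicates then receive a multiplicative scatter factor
`exp(N(0, 0.08))`, a random quadratic baseline (coefficient sd 0.004),
and additive noise with sd `0.003 · sqrt(8/resolution)` — finer
resolution, more points and more noise per point, emulating the
noise–resolution trade-off of FT-IR acquisition. ATR spectra are shaped
by a `1000/wavenumber` envelope, a proxy for the wavelength-dependent
penetration depth of the evanescent wave. These noise magnitudes were
chosen once as typical of bench FT-IR on neat oils (peak absorbances of
order 0.1–1 a.u., scatter of a few percent between replicate
preparations).

Reference values: fatty-acid responses are the composition entries;
iodine value is the composition-weighted sum of per-component
coefficients (0 for saturated acyls, 0.90 per % for one double bond,
1.81 for two, 2.74 for three — generator definitions that put pure-acid
iodine values at textbook magnitudes). Every other response blends a
defined linear function of composition with independent uniform noise in
its plausible pharmacopoeial range, weighted by a per-response *linkage*
in [0, 1]: 1.0 for the fatty acids and iodine value, 0.8 for
unsaponifiable matter, 0.1 for the acid, saponification, ester, hydroxyl
and peroxide values. The linkage gradient is the generator's central
design device: it builds in a known ordering of predictability that the
grid should — and does — recover.

Per-type mean compositions are drawn from a broad Dirichlet (α = 1.6,
0.9, 2.5, 0.25, 3.0, 0.7 over palmitic/stearic/oleic/elaidic/linoleic/
α-linolenic), giving type-to-type diversity comparable to real seed oils
(occasional high-linolenate types, rare trans content); within-type
jitter uses a concentrated Dirichlet (κ = 2000, a few percent relative).
All draws derive from a single seed through labelled sub-seeds, so
datasets are bit-reproducible and independent across noise streams.

What the generator does **not** emulate: interferogram-level instrument
physics (apodization, detector nonlinearity), atmospheric CO₂/H₂O
features, real ATR penetration physics, band shifts with matrix
composition, or correlated reference-method errors. Passing tests on
synthetic data therefore demonstrate that the pipeline is correct and
that it recovers structure *of the assumed linear form* at realistic
noise levels — not that any particular real oil panel would calibrate
equally well.

## Split rules

Oil types with one or two samples go entirely to calibration; types with
three or more keep two calibration representatives and send the rest to
validation, drawn uniformly at random with a required seed — but samples
holding the global minimum or maximum of *any* of the 13 responses are
kept in calibration where possible, so validation never extrapolates.
If excluding extreme holders leaves too few candidates, the draw falls
back to all samples of the type. The joint (all-13-responses) reading of
the exclusion was chosen because a per-response split would make the
sample partition response-dependent, and the study design uses one
partition for all models.

## Numerical conventions

- Axes are stored ascending; descending input is reversed on read.
- Axis uniformity is enforced to 1e-6 relative tolerance; nominal
  resolution accepts both the spacing = resolution and
  spacing = resolution/2 conventions within 50%.
- CSV round trips are exact: values are written with 17 significant
  digits and parsed with correctly-rounded base-R conversion.
- NIPALS early-stop tolerance: 1e-12 on `||X'y||`.
- `k` is capped at `min(20, n_cal − 1, q)` for fitting and
  `min(20, n_samples − 2, q)` in cross-validation.
- Replicate averaging is unweighted arithmetic.

## Problem sizes and runtime

The default synthetic dataset holds 111 spectra per block (37 × 3) with
851–3501 points depending on block; the full 7488-model screen takes
about 4–5 minutes on one CPU thanks to the row-space reduction and
per-block memoisation of preprocessing and selection. The test suite
exercises the complete grid once at the default conditions.

## Known limitations

- With only 8 validation samples, R²v is a noisy statistic, and the
  *maximum* R²v over hundreds of screened models has a heavy right
  tail: under near-null conditions (weakly linked responses), a handful
  of models can exceed R²v = 0.5 by chance in some realizations, always
  with the overfit signature of a near-perfect R²c. This is a property
  of exhaustive screening with small validation sets, not of any one
  model — it is precisely why the RANDOM control and the
  comparable-RMSEC/RMSEP check matter when reading the best-model
  tables, and why conclusions should rest on the ordering of responses
  rather than on any single threshold crossing.
- Selection precedes cross-validation (fitted once on the full
  calibration set), so RMSECV is mildly optimistic for STD/CORR; the
  validation metrics are unaffected.
- The generator's linear world cannot probe nonlinear detector or
  concentration effects; derivatives are unsmoothed differences, which
  amplify noise at 2 cm⁻¹ resolution by design.
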