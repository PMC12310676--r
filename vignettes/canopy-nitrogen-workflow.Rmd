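---
title: "Simulated satellite bands for canopy nitrogen estimation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulated satellite bands for canopy nitrogen estimation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canopysat)
```

## The problem

Open-access satellites (Landsat-8, Sentinel-2, GF-6) differ in which
visible/near-infrared (VNIR) bands they carry — most importantly in whether
they carry narrow red-edge bands. Before committing to real imagery, a useful
question is: *given the same canopy reflectance, which sensor's band set
retains the most information about canopy nitrogen?* The standard way to ask
it is band simulation: convolve ground-measured 1-nm canopy hyperspectra with
each sensor's spectral response functions (SRFs) to get "ideal-atmosphere"
band reflectances, then compare nitrogen-estimation skill across the
simulated sensors.

`canopysat` implements that comparison as a fully seeded pipeline for apple
canopy spectra across three phenological stages — new-shoot-growing (NGS),
new-shoot-stop-growing (NSS) and autumn-shoot (ASS). Because the underlying
field data are not publicly deposited, the package includes a synthetic
spectral generator with a *known* nitrogen-to-spectrum coupling, so every
downstream stage is testable against planted ground truth.

## The synthetic canopy generator

### Nitrogen

Per stage, nitrogen (mg/g) is drawn from a truncated normal on
[2.0, 3.9] mg/g with sd 0.30. The stage means are fixed at 3.04 (NGS), 2.82
(NSS) and 2.60 (ASS) mg/g — the reported stage averages of the emulated
study system — and the sd/bounds are chosen so that ±3 sd roughly spans the
reported overall range (2.02–3.83 mg/g). The truncated normal's *location*
parameter is solved numerically (via `truncnorm::etruncnorm` and `uniroot`)
so the distribution mean equals the target exactly: with a naive location of
2.60 the asymmetric truncation at 2.0 would bias the ASS mean by +0.017 mg/g,
most of the calibration tolerance.

### Spectra

Each spectrum lives on the 350–2500 nm grid at 1 nm (2151 points) and is
assembled from interpretable parts:

* a **visible continuum** (0.115 plus a small green peak at 550 nm);
* two **chlorophyll absorption wells** (gaussians at 450 and 670 nm) whose
  fractional depth saturates with the chlorophyll index,
  `depth = jitter * chl / (chl + 3)`;
* a **logistic red edge** between ~680 and 780 nm whose inflection shifts
  longward with chlorophyll: `690 + 45 * chl / (chl + 50)` nm;
* a **NIR plateau** at the stage amplitude (0.52 / 0.46 / 0.40 for
  NGS / NSS / ASS, encoding the observed stage brightness ordering) times a
  per-sample lognormal structure factor (sdlog 0.04);
* fixed **water-absorption wells** near 1450 and 1940 nm on a smoothly
  declining SWIR branch;
* additive gaussian noise (sd 0.004, the scale of averaged, smoothed field
  spectroradiometer canopy measurements), then clipping to [0, 1].

Chlorophyll is linked to nitrogen linearly
(`chl = max(0, 16 N − 14 + ε)`, ε ~ N(0, 1.5)), the simplest monotone
coupling consistent with nitrogen being a chlorophyll constituent. Over the
nitrogen range this puts the chlorophyll index between roughly 18 and 48.

### Why the red edge is the planted signal

Two deliberate variance components make band-pair screening recover the
red-edge structure the way field studies do:

* the **pigment jitter** (per-sample lognormal, sdlog 0.06, multiplying well
  depth) injects visible-region variance unrelated to nitrogen. Combined
  with the strongly saturating well depth, it caps the correlation any
  visible–visible normalized difference can reach;
* the **structure factor** scales the whole NIR plateau, so a normalized
  difference of two bands on the red edge/NIR shoulder cancels it almost
  exactly, while the red-edge inflection — a clean function of chlorophyll
  alone — moves the band values against each other.

The result (verified in the tests at n = 500, zero noise) is that
|r(N, ND(red-edge pair))| exceeds |r| of every visible–visible pair, so the
screening, ablation and sensor-ranking stages all have a recoverable ground
truth. What a green test establishes is exactly that recovery — not any
field-data accuracy. Absolute R²/RMSE values on synthetic data are
properties of the generator and are deliberately not compared with the
emulated study's field values.

### Seeding

Every random stream derives from one user seed through
`derive_seed(seed, stream)`, an affine map modulo 2^31 − 1: nitrogen draws,
the chlorophyll-link noise, each sample's spectrum draws, split assignment,
CV folds and network initialisation all get distinct sub-seeds. Identical
configuration + seed gives bit-identical artifacts end to end (the pipeline
manifest records md5 checksums to prove it).

## Smoothing

Field protocols smooth measured canopy spectra but rarely name the method.
The package uses Savitzky–Golay with default window 15 points, polynomial
order 3 — the community default for field-spectroradiometer spectra — as a
documented choice, not an inference about any particular study. Coefficients
are computed by local least squares; edge points are fitted on the
asymmetric leading/trailing windows, so polynomials of degree ≤ order pass
through unchanged everywhere (the property the tests assert). Output is
clipped to [0, 1]. Idempotence is *not* claimed.

## Sensor simulation

Band reflectance is the SRF-weighted mean of the spectrum,

$$\rho_{band} = \frac{\int s(\lambda)\,\rho(\lambda)\,d\lambda}
                     {\int s(\lambda)\,d\lambda},$$

evaluated by the trapezoidal rule on the native 1-nm grid (fine relative to
every band width, so no interpolation is needed). This is exact for linear
spectra — the test anchor: a ramp `ρ = λ/2500` through the 845–885 nm boxcar
gives 865/2500.

True SRF curves for the three sensors are published as plots, not tables, so
shapes are synthesized and therefore live in editable JSON configs rather
than code: boxcars for the range-defined sensors (Landsat-8, GF-6) and
gaussians for centre-defined Sentinel-2. Sentinel-2 FWHM defaults use 15 nm
for the three red-edge bands (their distinguishing narrowness) and
approximate instrument bandwidths elsewhere; all are per-band editable. The
VNIR filter keeps boxcar bands fully inside 400–1000 nm and gaussian bands
centred inside it, reproducing the published VNIR counts: 5 (Landsat-8,
coastal–NIR), 10 (Sentinel-2, 443–945 nm incl. the water-vapour band),
8 (GF-6, incl. its purple-edge and yellow-edge bands). GF-6's yellow-edge
band is bundled as 590–630 nm (the sensor parameter table's value; an
alternative 520–600 nm figure circulates but conflicts with the green band).

## Band-pair screening

For every unordered band pair the package computes the normalized
difference `ND = (r_i − r_j)/(r_i + r_j)` per sample and its Pearson
correlation with nitrogen. Conventions:

* pairs are stored with the earlier band (sensor order) first; selection is
  by |r|, so orientation is irrelevant (swapping flips only the sign);
* samples with a zero-sum denominator are excluded pairwise, with a message;
* the Pearson denominator uses the square root of the product of centered
  sums of squares (the definition that actually yields a correlation
  in [−1, 1]);
* ties on |r| break on first pair in band order.

## PLSR

The band-combination evaluation uses a from-scratch single-response NIPALS
PLSR: predictors autoscaled, response centered, one component per
weight/score/loading extraction with deflation of both blocks, coefficients
back-transformed to the original scale. Numerical choices:

* the single-response inner loop converges in one pass; the iteration is
  retained defensively (tolerance 1e-10, cap 500);
* if deflation exhausts the X'y covariance before the requested component
  count (e.g. perfectly collinear bands), extraction stops and the model
  keeps the components found — the behaviour chemometrics packages adopt —
  rather than failing;
* default component count `min(3, #bands)`: combination tables compare
  ≤10-band sets whose informative rank is low; a uniform small count keeps
  combinations comparable. Zero-variance predictors are an error naming the
  band.

Combination reports quote *training* R² (the single-R² convention of
combination tables); ablation tables add the drop against the base
combination. Validation-split R² is available by evaluating on held-out
rows explicitly.

## Nitrogen estimators

Both estimators standardize predictors *and* response on training-set
statistics (validation data pass through the training transform — no
leakage), and are deterministic under a seed.

**SVM**: epsilon-SVR with RBF kernel. No SVM library exists in the target
environment, so the dual quadratic program is solved exactly with
`quadprog::solve.QP` (a 1e-6-scaled ridge keeps the PSD dual Hessian
positive definite for the solver; the bias comes from the free support
vectors' KKT conditions). Hyperparameters follow a small fixed grid —
C ∈ {0.1, 1, 10, 100}, γ ∈ {0.01, 0.1, 1}, ε = 0.1 on the standardized
response — selected by seeded 5-fold CV on the training set; ties break on
grid order.

**BPNN**: one hidden layer of `2B + 1` logistic units (B = band count, the
classical heuristic for small tabular regressors), linear output, full-batch
gradient descent with momentum 0.9, learning rate 0.1, ≤2000 epochs. A
seeded 20% internal holdout drives early stopping (patience 200, best
weights kept); if the cap is reached while still improving, a warning is
emitted and the best-so-far weights returned.

**Evaluation design**: 100 samples per stage split 60/40 into training and
validation by a seeded uniform draw; *one split per stage is shared across
all sensors and models*, so sensor and model comparisons are paired. The
full design is 3 sensors × 2 models × 3 stages × 2 splits = 36 rows. R²
defaults to `1 − SSres/SStot`; the explained-variance ratio
`SSreg/SStot` — which equals it for least-squares linear fits but can exceed
1 for biased nonlinear predictors — is available as `mode = "eq3"` for
convention-matching. RMSE is the plain root mean square error in mg/g.
Per-sensor "average" accuracies are arithmetic means over the three stages.

## Known limitations

* The generator is parametric, not radiative-transfer-based: no PROSPECT /
  PROSAIL leaf/canopy physics, no soil background, no atmosphere, no
  illumination geometry. Stage differences are encoded only through the
  nitrogen distribution and the NIR amplitude.
* Synthesized SRF shapes (ideal boxcar/gaussian) stand in for the agencies'
  measured response curves; the JSON configs isolate that assumption.
* Absolute estimator accuracies on synthetic data say nothing about field
  accuracy; only the *structural* findings (red-edge dominance in screening,
  red-edge ablation cost, red-edge-equipped sensors ranking above Landsat-8)
  are asserted, each across repeated seeds.
* The third stage's field naming varies between sources ("autumn
  shoot-growing" vs "autumn shoot stop-growing"); the package treats the two
  as synonyms under the code `ASS`.
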