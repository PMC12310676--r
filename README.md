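# canopysat

Satellite band simulation and canopy nitrogen estimation from 1-nm canopy
hyperspectra, for researchers comparing how well open-access sensors
(Landsat-8, Sentinel-2, GF-6) can monitor orchard nitrogen status across
phenological stages.

Ground-measured canopy reflectance ρ(λ) is convolved with each sensor's
per-band spectral response function s(λ) to simulate ideal-atmosphere band
reflectance,

    ρ_band = ∫ s(λ) ρ(λ) dλ / ∫ s(λ) dλ,

restricted to the visible/near-infrared band subsets (5 Landsat-8,
10 Sentinel-2, 8 GF-6 bands). Nitrogen-sensitive band pairs are screened by
the Pearson correlation between each pair's normalized difference
(rᵢ − rⱼ)/(rᵢ + rⱼ) and measured nitrogen; band combinations are compared
with a from-scratch NIPALS partial least squares regression (single-band and
red-edge ablations); and epsilon-SVR (RBF kernel, CV grid search) and a
single-hidden-layer backpropagation network estimate nitrogen from all VNIR
bands on paired, seeded 60/40 train/validation splits, scored by
R² = 1 − SSres/SStot and RMSE (mg·g⁻¹).

Because the emulated study's field data are not deposited, the package ships
a seeded synthetic canopy generator (100 samples per stage; stage nitrogen
means 3.04 / 2.82 / 2.60 mg·g⁻¹ on [2.0, 3.9]; chlorophyll-driven absorption
wells and red-edge shift; stage-ordered NIR brightness) whose planted
nitrogen→spectrum coupling gives every stage of the pipeline a recoverable
ground truth. See `vignettes/canopy-nitrogen-workflow.Rmd` for the model and
every default.

## Worked example

The numbered drivers under `analysis/` run the whole study design
(`Rscript analysis/01_simulate.R 1`, then `02`…`06`; the argument is the
master seed). With seed 1, step 3 prints the strongest normalized-difference
pair per sensor and stage:

```
NSS landsat8  best pair coastal/red  r = +0.618
NSS sentinel2 best pair RE1/NIR1  r = -0.953
NSS gf6       best pair NIR/RE1  r = +0.952
NSS overall strongest index: ND(RE1, NIR1), |r| = 0.953
```

— the strongest indices always involve red-edge bands, and only the sensors
that carry them reach |r| ≈ 0.95. Step 4 quantifies the same structure in
PLSR terms (training R² of the full Sentinel-2 band set vs the set without
its red-edge bands):

```
NSS sentinel2 full-band R2 0.907 -> 0.658 without red edge (drop 0.249)
```

and step 6 ranks sensors by mean validation accuracy across stages
(SVM, seed 1):

```
          r2_train rmse_train r2_val rmse_val
gf6          0.915      0.087  0.828    0.124
sentinel2    0.920      0.084  0.806    0.134
landsat8     0.573      0.193  0.289    0.246
```

The red-edge-equipped sensors clearly outrank Landsat-8; absolute values are
properties of the synthetic generator, not field estimates. The same run is
available as one call, `run_pipeline(pipeline_config(seed = 1))`, which also
writes a checksummed manifest.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

regenerates, from fresh seeded draws (n = 10,000 per stage), the mean
nitrogen concentration of each phenological stage under the default
generator parameters and writes them as JSON.
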