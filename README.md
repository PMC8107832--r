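# nucscatter

Light-scattering signatures of chromatin texture in cell nuclei.

Chromatin reorganization during precancerous progression changes the
spatial correlation of refractive-index fluctuations inside cell nuclei.
`nucscatter` is an R package for studying how those fluctuations imprint on
azimuth-resolved elastic light-scattering patterns, and for estimating the
fluctuation correlation length directly from stained-nucleus images. It is
aimed at researchers in tissue optics, quantitative histopathology and
flow-cytometry signal modelling.

## What it computes

**Forward pipeline.** Nuclei are modelled as spheres or ellipsoids of mean
refractive index *n* in cytoplasm *n<sub>out</sub>*, with internal
fluctuations *n*(**x**) = *n* + *δn·g*(**x**), where *g* is a unit-variance
Gaussian random field with correlation

&nbsp;&nbsp;&nbsp;&nbsp;*C*(*r*) = exp(−*r*²/*l<sub>c</sub>*²),

*l<sub>c</sub>* the correlation length (μm) and *δn* the fluctuation
standard deviation. Fields are generated spectrally or by the turning-bands
method. For an 800-nm x-polarized plane wave travelling along +z, the
far-field intensity *I*(θ, ϕ) on a 1° × 1° grid (θ 0–180°, ϕ 0–360°) is
computed with a first-Born FFT solver — the 3-d Fourier transform of the
scattering potential sampled on the Ewald sphere, times the dipole
polarization factor (1 − sin²θ cos²ϕ) — validated against a built-in
Lorenz–Mie series and the closed-form sphere form factor. Rigorous solvers
can be plugged in through a backend registry.

**Texture features.** Each pattern's log-intensity is contrast-stretched to
0–255, quantized to 8 gray levels, and reduced to gray-level co-occurrence
matrices at offset 1 along θ or ϕ. The Haralick contrast
Σ|i−j|²·p(i,j) along ϕ (azimuthal contrast), along θ (polar contrast), and
their ratio contrast<sub>ϕ/θ</sub> are computed over small-angle (0–40°),
side (40–140°) and high-angle (140–180°) ranges, with three-replicate
mean ± standard-error aggregation and monotone-trend checks across
parameter sweeps.

**Image analysis.** `nucleus_lc()` estimates *l<sub>c</sub>* from a 2-d
optical-density image (0.34 μm/pixel by default): row/column
autocorrelations of three regions of interest are fitted with
*C*(*r*) = exp(−*r*²/*l<sub>c</sub>*²) (amplitude fixed at 1), keeping fits
with ≥ 4 points and R² > 0.95. A synthetic-image generator with known
ground truth supports estimator validation end to end.

## Worked example

```r
library(nucscatter)

# one stochastic nucleus: dense sphere defaults, lc = 0.7 um, dn = 0.020
spec <- nuclear_model_spec("sphere", R = 4.0, n = 1.40, n_out = 1.36,
                           lc = 0.7, delta_n = 0.020, spacing = 0.1, seed = 1)
vol <- build_model(spec)
vol
#> <refractive_index_volume> 85x85x85 grid @ 0.1 um; sphere R=4.00 um, n=1.400 in n_out=1.360,
#>   lc=0.70 um, delta_n=0.020 (realized sd 0.0186), seed 1

pat <- solve_pattern(vol, plane_wave(800, 1.36), backend = "born")
fs <- feature_set(pat)
fs[, c("range", "mean_intensity", "contrast_theta", "contrast_phi", "contrast_ratio")]
#>         range mean_intensity contrast_theta contrast_phi contrast_ratio
#> 1 small_angle      0.8601178      0.2849306   0.04293770      0.1506953
#> 2        side     -2.4237550      0.2978889   0.06406685      0.2150696
#> 3  high_angle     -2.6734913      0.0981250   0.02853455      0.2907979
```

The side-range azimuthal contrast (0.064) measures how often and how
strongly the stretched log-intensity jumps between neighbouring azimuthal
degrees in the 40–140° band; its ratio to the polar contrast (0.22) is the
feature that tracks *l<sub>c</sub>* and *δn* while staying insensitive to
nuclear size and mean index. Recovering the correlation length from a
synthetic image:

```r
gen <- make_nucleus_image(synthetic_image_spec(lc_true = 0.7, seed = 41))
nucleus_lc(gen$image, gen$rois)
#> <lc_estimate> lc = 0.73 um (2.15 px), 3/3 ROIs used
```

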