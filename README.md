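# spadspec

Chemometric estimation of wheat leaf chlorophyll (SPAD) from canopy
hyperspectral reflectance, built for monitoring vegetation stress from CO₂
microleakage (e.g. above geological carbon-storage sites). Slow sub-surface
CO₂ escape depresses chlorophyll in the overlying canopy; the spectral
signature — a taller green peak near 550 nm, a blue-shifted red edge — is
detectable long before visible damage, and a calibrated reflectance→SPAD
model turns a spectroradiometer trace into a leaf-greenness estimate without
touching the plant.

The package is aimed at plant-phenotyping and remote-sensing researchers who
want the full pipeline as composable, pipe-friendly R functions:

1. **Preprocessing** — quality control (missing channels, out-of-bounds
   reflectance, abnormal jumps), five-point weighted moving-average
   smoothing, 1 nm resampling, range cropping.
2. **Fractional-order differentiation** — Grünwald–Letnikov (G-L)
   differentiation of each spectrum at orders α = 0, 0.1, …, 2 (21
   transforms). For a reflectance sequence r on a uniform grid with spacing
   h, channel i of the order-α derivative is

   D^α r(i) = h^(−α) · Σₖ₌₀..i wₖ · r(i−k),  w₀ = 1, wₖ = wₖ₋₁ (k−1−α)/k,

   i.e. wₖ = (−1)ᵏ C(α, k); α = 1 and α = 2 reduce to the classical first
   and second differences. Non-integer orders expose fine gradient structure
   that raw reflectance and integer derivatives miss.
3. **Band selection** — the successive projections algorithm (SPA): grow a
   chain of wavelengths, each maximizing its norm after projection onto the
   orthogonal complement of the chain so far, then keep the chain whose
   bands give the lowest validation RMSE. Ten minimally collinear,
   SPAD-sensitive bands replace ~950 channels.
4. **Calibration** — multiple linear regression (MLR) and partial least
   squares regression (PLSR, NIPALS) of SPAD on the selected bands, scored
   by R² = 1 − SSres/SStot and RMSE = √(Σ(ŷᵢ−yᵢ)²/n).
5. **Order sweep** — repeat selection + calibration at every α per
   treatment group, pick the order maximizing validation R², and report the
   percentage change relative to the raw (α = 0) spectra.

Because the motivating field campaign's raw data are not publicly deposited,
the package ships a first-class synthetic generator
([`synth_config()`], [`generate_dataset()`]) that reproduces the study
design — four treatment groups (control and 1/3/5 L·min⁻¹ leakage) with
group-wise truncated-normal SPAD distributions — and the qualitative physics
the method exploits: green-peak height falls and the red-edge inflection
moves red as SPAD rises, chlorophyll absorption wells deepen, plus Gaussian
channel noise and "burr" spikes. Every stage is therefore testable end to
end.

## Worked example

```r
library(spadspec)

cfg <- synth_config(n_per_group = 30, seed = 42)   # 4 groups x 30 samples
run <- run_spad_pipeline(config = cfg)             # QC -> smooth -> crop ->
                                                   # 21-order x 2-model sweep
run$optimal
#> # A tibble: 8 × 5
#>   group   model order    r2  rmse
#>   <chr>   <chr> <dbl> <dbl> <dbl>
#> 1 1L      mlr     0   0.995 0.890
#> 2 1L      plsr    0   0.995 0.837
#> 3 3L      mlr     0   0.992 0.626
#> 4 3L      plsr    0   0.992 0.626
#> 5 5L      mlr     0   0.998 0.568
#> 6 5L      plsr    0.2 0.998 0.483
#> 7 control mlr     0   0.949 0.700
#> 8 control plsr    0   0.963 0.594
```

One row per (treatment group, model): the differentiation order with the
highest validation-set R², its R² and its RMSE (SPAD units). On this clean
synthetic dataset the latent SPAD→spectrum encoding is recovered almost
perfectly (R² 0.95–0.998 from 10 validation samples per group), and the raw
spectra (order 0) are already near-optimal — fractional orders earn their
keep on data whose signal is subtler than the generator's. The control group
is hardest: its SPAD spread (sd ≈ 3.2) is a fifth of the stressed groups',
so the same absolute error costs far more R².

Group-level spectral features mirror stressed-canopy physics:

```r
spectral_features(run$data) |>
  dplyr::group_by(group) |>
  dplyr::summarise(green_peak = mean(green_peak_height),
                   red_edge = mean(red_edge_position))
#>   group   green_peak red_edge
#> 1 1L           0.186     716.
#> 2 3L           0.201     711.
#> 3 5L           0.196     714.
#> 4 control      0.162     724.
```

Stressed groups (lower SPAD) show taller green peaks and blue-shifted red
edges relative to the control. `plot_sweep(run$sweep)`,
`plot_predictions(run)` and `plot_spectra(run$data)` draw the corresponding
figures, and `write_report(run, "out/")` persists every table plus a JSON
manifest, bit-reproducibly.

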