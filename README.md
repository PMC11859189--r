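# lagoonwq

Empirical water-quality retrieval from four-band high-resolution satellite
imagery of hypertrophic inland waters.

Shallow hypertrophic lagoons vary on scales of tens of metres — far below
the pixels of the ocean-colour sensors that carry dedicated water-quality
algorithms. High-resolution imagers resolve those scales but offer only
four broad bands (blue, green, red, NIR), so retrieval has to be
*empirical*: regress field measurements on two-band reflectance indices,
pick the best index/function pair by cross-validation, and map it. This
package implements that workflow for five variables — chlorophyll-a
(Chl-a, µg/L), Secchi disk depth (SDD, m), and total / inorganic / organic
suspended matter (TSM / PIM / POM, mg/L; TSM = PIM + POM) — for users in
inland-water remote sensing and limnology.

## What it does

- **Radiometry** — DN → TOA radiance via per-band gain/bias (both gain
  conventions), exact inversion of the Lambertian atmospheric coupling
  `L = L0 + (I0·Tg·T↓↑/π)·ρ/(1 − Sρ)` to surface reflectance, band
  convolution of in-situ hyperspectral Rrs, correction-validation
  statistics.
- **Matchups** — ROI mean spectra (100–150 water pixels) paired with field
  samples within a 3-day window; spectral-stability t-test;
  normality-gated Pearson/Spearman cross-correlation.
- **Index calibration** — all 18 two-band indices (12 simple ratios
  `Ra/Rb` + 6 normalized differences `(Ra−Rb)/(Ra+Rb)`) × five fit
  families (linear, exponential, power, logarithmic, polynomial), each
  scored by seeded 10-fold cross-validated RMSE (plus R², NRMSE as % of
  the observed range, MAE, bias) and ranked.
- **Retrieval mapping** — a registry of the published best models, e.g.
  `Chl-a = 323.77·(B4−B1)/(B4+B1) + 198.95`, plus the Sentinel-2
  literature models; NIR-threshold water masking; clamped thematic maps
  with full pixel accounting; sensor-comparison tables; seasonal map
  series.
- **Synthetic data** — field campaigns drawn from a latent trophic factor
  (Chl-a–SDD correlation −0.845, TSM–POM ≈ 0.87, exact TSM = PIM + POM),
  reflectance built by inverting the published models, and DN-level
  scenes with ground truth, so the entire chain is testable offline.

## Worked example

```r
library(lagoonwq)

cfg <- pipeline_config(seed = 42, n_samples = 200, noise_cv = 0.05,
                       scene_shape = c(100, 100), water_fraction = 0.8)
rep <- run_pipeline(cfg)
rep
#> <wq_run_report> seed 42, config 00548146
#>   samples: 200, matchups: 200
#>   chl_a best: (B4-B1)/(B4+B1) linear (CV RMSE 12)
#>   ...

rep$rankings$chl_a$top[1:3, c("band_comb", "family", "formula", "rmse")]
#>         band_comb      family                     formula  rmse
#> 1 (B4-B1)/(B4+B1)      linear       y = 315.71x + 198.539 12.00
#> 2           B1/B4 exponential y = 437.031*exp(-0.782763x) 12.04
#> 3 (B4-B1)/(B4+B1)  polynomial y = -8.25879x^2 + ...       12.08
```

The search recovers the generating model: the synthetic campaign encodes
chlorophyll through the published line `y = 323.77x + 198.95` on
ND(B4,B1), and with 5% reflectance noise the top-ranked combination is
that index with a linear fit, coefficients within a few percent
(slightly attenuated, as expected when noise enters the regressor). The
CV RMSE of 12 µg/L is the held-out retrieval error at this noise level,
and NRMSE ≈ 4% expresses it as a share of the 21–331 µg/L range.

```r
rep$maps$chl_a$counts
#>       masked      invalid  clamped_low clamped_high     in_range
#>         2000            0            0            0         8000
```

The thematic map accounts for every pixel of the 100 × 100 scene: 2000
land pixels masked by the NIR threshold, 8000 water pixels mapped in
range, none clamped.

```r
fs <- simulate_field_campaign(sim_config(n_samples = 1000, seed = 42))
cm <- cross_correlate(fs)
round(c(cm$r["chl_a", "sdd"], cm$r["tsm", "pom"]), 3)
#> [1] -0.850  0.858
```

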