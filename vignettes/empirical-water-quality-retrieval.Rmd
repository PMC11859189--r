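---
title: "Empirical water-quality retrieval from four-band imagery: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Empirical water-quality retrieval from four-band imagery: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lagoonwq)
```

## The problem

Hypertrophic inland waters — shallow lagoons with persistently extreme
phytoplankton biomass — change on scales of tens of metres, below the pixel
size of the ocean-colour sensors that carry purpose-built water-quality
algorithms. High-resolution Earth-observation satellites resolve those
scales but offer only a handful of broad bands (here blue 450–520 nm, green
530–590 nm, red 630–700 nm, NIR 752–885 nm at 2.8 m), too few for
semi-analytical inversion. The pragmatic alternative is *empirical
retrieval*: regress field-measured water-quality variables — chlorophyll-a
(Chl-a, µg/L), Secchi disk depth (SDD, m), and total/inorganic/organic
suspended matter (TSM/PIM/POM, mg/L, with the gravimetric identity
TSM = PIM + POM) — on two-band reflectance indices, select the best
index/function pair by cross-validation, and map the winning model over
water pixels.

This package implements that workflow end to end, plus a synthetic-data
generator that stands in for field campaigns and imagery, so every stage is
testable without downloads.

## Radiometric model

Raw pixels arrive as digital numbers (DN). Per band,

$$L = \mathrm{DN}/\mathrm{GAIN} + \mathrm{BIAS}$$

converts to top-of-atmosphere radiance (`dn_to_radiance`). Because vendor
documentation is ambiguous between dividing and multiplying by the gain,
both conventions are supported (`convention = "divide"` is the default, the
NAOMI-class product convention). Surface reflectance $\rho$ then follows
from the Lambertian coupling

$$L = L_0 + \frac{I_0\,T_g\,T_{\downarrow\uparrow}}{\pi}\,
      \frac{\rho}{1 - S\rho},$$

with path radiance $L_0$, effective solar irradiance $I_0$ (already scaled
by Earth–Sun distance and solar zenith cosine — callers supply the
composite), gaseous transmittance $T_g$, two-way scattering transmittance
$T_{\downarrow\uparrow}$, and spherical albedo $S$. These terms come from a
radiative-transfer code run for the acquisition conditions; computing them
is out of scope here — they are pipeline inputs. `invert_surface_reflectance`
applies the exact algebraic inverse
$\rho = y/(1+Sy)$ with $y = \pi(L-L_0)/(I_0 T_g T_{\downarrow\uparrow})$;
the pair is identity to machine precision, which the test suite asserts to
1e-12 on a parameter grid. Negative retrieved reflectance (over-corrected
dark water) is *flagged, not zeroed*, so that index computations can
exclude it deliberately; values are clipped to $[-0.05, 1]$ with counts
recorded.

In-situ hyperspectral Rrs is band-averaged with a rectangular spectral
response (`convolve_to_bands`); true response functions are not published
for this sensor, and for validation scatter statistics the rectangular
approximation is adequate.

## Matchups and supporting statistics

`build_matchups` pairs each field sample with the nearest-in-time scene
within a 3-day window (the conventional limit for stable inland waters;
equidistant candidates resolve to the earlier scene). `extract_roi` grows a
square window centred on the sampling point and averages reflectance over
100–150 water pixels. The protocol fixes only the pixel-count range, not
the window shape; squares were chosen for translation invariance. The
window side is the largest whose water-pixel count stays ≤ 150, accepted if
the count also reaches 100 — on open water this gives a 12 × 12 window (144
pixels). `spectral_stability_test` supports the lag rule with a paired
Student's t-test on the two dates' spectra (a pooled two-sample variant is
available; the paired form is the default since band values are naturally
paired). `cross_correlate` reproduces the field-table practice of gating
Pearson vs Spearman on a normality test; Shapiro–Wilk at α = 0.05 is used
because it is the standard small-sample choice.

## Index calibration

`enumerate_indices` generates every two-band combination: 12 ordered simple
ratios $R_a/R_b$ and 6 normalized differences $(R_a-R_b)/(R_a+R_b)$ in a
canonical orientation (longer wavelength first). The reversed ND
orientation is a sign flip absorbed by the fitted slope, so enumerating
both would double the work without changing any ranking — a property the
tests assert exactly.

Five function families are fitted per index — linear, exponential
($ae^{bx}$), power ($ax^b$), logarithmic ($a + b\ln x$), and polynomial
(degree 2 by default; no degree is standard in this literature and degree 2
is the smallest that adds curvature). Nonlinear families are fitted by
their linearizing transforms; all statistics are computed on the original
scale. Validation statistics follow the field's conventions:
R² as squared Pearson correlation of observed vs predicted, RMSE, MAE,
bias = mean(predicted − observed), and NRMSE = 100·RMSE/(observed min–max
range). The range normalizer is a verified inference: it is the only
definition consistent with the published RMSE/NRMSE pairs for all five
variables (e.g. 100·50.8/(331−21) ≈ 16.4 → printed "16"), which the
acceptance suite recomputes.

`crossvalidate` is a seeded 10-fold scheme: uniform shuffle, folds as equal
as possible (21 samples → folds of 2 or 3), fit on k−1 parts, evaluate on
the held-out part, average across folds. Bias is pooled over all held-out
predictions, and NRMSE is normalized by the full-sample range. Fold-level
R² is degenerate on 2–3-point folds (any non-constant prediction correlates
perfectly), so a pooled held-out R² is emitted alongside the fold mean; the
ranked tables display the pooled form.

`rank_indices` evaluates all 18 × 5 combinations, drops combinations with
missing index values (zero denominators, flagged reflectance) with a
failure log rather than imputing, and sorts by cross-validated RMSE with
ties broken by higher R², then index name — a deterministic total order.

### A caution on family selection

Cross-validated RMSE ranking reliably identifies the best *index*, but the
best *family* on near-linear data is genuinely unstable: the degree-2
polynomial nests the linear family, and a single k-fold comparison prefers
the spurious extra term in roughly 15% of realizations — a well-known
inconsistency of CV model selection. Under multiplicative noise, log-scale
fits (exponential on the reciprocal ratio) also compete, since
linearization implicitly weights by relative error. On synthetic matchups
with an exactly linear ND(B4,B1) truth and 5% noise, the generating
index+family pair ranks first in about 70% of seeds; the index alone, and
the recovered coefficients (within 2%), are far more stable. Users should
read the family column of a ranked table as "adequate", not "identified".

## The published-model registry

`published_registry` carries the calibrated best-per-variable algorithms
for the four-band sensor —

| variable | index | model |
|---|---|---|
| Chl-a (µg/L) | (B4−B1)/(B4+B1) | y = 323.77x + 198.95 |
| SDD (m) | (B4−B1)/(B4+B1) | y = −0.2539x + 0.2608 |
| TSM (mg/L) | B1/B4 | y = −38.259x + 129.38 |
| PIM (mg/L) | (B3−B1)/(B3+B1) | y = 116.08x + 31.36 |
| POM (mg/L) | B3/B4 | y = −18.775x + 70.925 |

— and the Sentinel-2 literature models used for sensor comparison (six-band
spectra named R490…R783, including the three-band Chl-a model). The TSM
observed range is stored both as printed (50–136 mg/L) and as 39–136 mg/L;
the latter is used for NRMSE normalization because it alone reproduces the
printed 11%. Thematic-map outputs are clamped to the observed range
extended by 50% headroom above the maximum and floored at zero (SDD at
0.01 m) — map palettes are bounded, and clamp counts are always reported so
nothing is silently lost.

`water_mask` classifies water by low NIR reflectance (B4 < 0.2 by default:
even hypertrophic, sediment-laden water stays well below vegetated-land NIR
at this threshold). `apply_model` is pixelwise-pure; masked, invalid,
clamped and in-range counts partition the pixel grid exactly.

## The synthetic generator

`simulate_field_campaign` draws the five variables from a shared latent
trophic state $z \sim U(0,1)$: each scaled variable is a convex combination
$q = wz + (1-w)u$ with an independent uniform $u$, so values stay exactly
inside the configured ranges (defaults: Chl-a 21–331 µg/L, SDD 0.16–0.42 m,
TSM 39–136 mg/L, PIM 2–75 mg/L, POM 7–60 mg/L) and the population
correlation between two variables is an explicit function of their
loadings. The loadings (0.7 for Chl-a and SDD on opposite ends of $z$, 0.8
for TSM, 0.65 for POM) put the Chl-a–SDD correlation at −0.845 and
TSM–POM near 0.87, matching the observed correlation structure of the
study system. PIM is the gravimetric residual TSM − POM, so the additivity
identity holds by construction; its range is therefore induced rather than
imposed, and under the default ranges it stays positive with realistic
spread.

`bio_optical_forward` builds reflectance by *inverting the published
models*: the Chl-a equation fixes ND(B4,B1) around a configurable blue-band
baseline (0.06 — turbid-water blue reflectance), the POM equation fixes
B3/B4, and B2 is the mean of B1 and B3 (the green band carried no retrieval
information in this band set, so nothing constrains it). With four bands
and a fixed baseline there are only two free degrees of freedom, so only
Chl-a and POM can be encoded exactly; SDD, TSM and PIM are related to the
spectrum only statistically, through their correlation with the encoded
pair. That is a deliberate trade: exact round-trip recoverability for the
two headline models, realism for the rest. Multiplicative Gaussian noise at
`noise_cv` (default 0.05 — a modelling choice; the source data report
ranges and correlations but no scatter magnitude) perturbs all bands.

`simulate_scene` drives the same variable construction with spatially
smoothed latent fields (Gaussian-blurred white noise, rank-transformed to
uniform margins; correlation length 8 pixels by default), places a
land block (bright NIR, reflectance 0.26) covering `1 − water_fraction` of
the columns, pushes reflectance through the forward Lambertian model with
plausible clear-sky atmospheric terms, and quantizes to 12-bit DNs with
gains that span the scene's radiance range. On a default 100 × 100
noiseless scene the full chain — simulate → calibrate → invert → apply the
published Chl-a and POM models — returns to truth within 0.8% per pixel
(worst case; mean ≈ 0.05%), entirely DN-quantization error; before
quantization the round trip is exact to 1e-6 relative.

What the generator does **not** emulate: inherent-optical-property
radiative transfer in water, sun glint, adjacency effects, clouds, or
geolocation error. Passing tests therefore demonstrate the correctness and
statistical behaviour of the *pipeline*, not the field accuracy of any
retrieval model on real imagery.

## Orchestration and problem sizes

`run_pipeline` sequences simulate → calibrate → map → compare under one
master seed, with a config hash recorded in the run report; two runs from
the same configuration are identical. The pipeline is an R-level interface
(plus YAML configs via `read_pipeline_config`) because its users work
inside R; there is no shell entry point.

Default problem sizes were chosen to make the statistics stable while
keeping a full test run fast: campaigns of 200 samples for calibration
experiments, 1000 for correlation checks, 100 × 100 scenes for mapping
round trips, 100 seeded repetitions for the selection-frequency and
CV-noise-consistency experiments.

## Known limitations

- Family selection by single k-fold CV is inconsistent for nested families
  (see above); a one-standard-error rule or repeated CV would stabilize it
  but is deliberately not applied, to keep the selection rule identical to
  the workflow being reproduced.
- Scene I/O uses plain multi-band float TIFF with a JSON metadata sidecar,
  not georeferenced GeoTIFF; geotransform and CRS travel in the sidecar.
- The Sentinel-2 registry models require six-band spectra; no spectral
  resampling between sensors is attempted.
- Atmospheric terms are inputs; no radiative-transfer computation, BRDF or
  adjacency correction is provided.
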