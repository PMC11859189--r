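Package: lagoonwq
Title: Empirical Water-Quality Retrieval from Four-Band High-Resolution
    Satellite Imagery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deriving and applying empirical water-quality
    retrieval algorithms (chlorophyll-a, Secchi disk depth, and total,
    inorganic and organic suspended matter) from four-band high-resolution
    multispectral imagery of hypertrophic inland waters. Covers radiometric
    calibration from digital numbers to top-of-atmosphere radiance,
    inversion of the Lambertian atmospheric-correction equation to surface
    reflectance, matchup construction between region-of-interest mean
    spectra and field samples under a time-window rule, exhaustive
    two-band simple-ratio and normalized-difference index calibration with
    k-fold cross-validation, a registry of published retrieval models,
    NIR-threshold water masking and thematic mapping, and a synthetic-data
    generator that emulates the statistical and bio-optical structure of a
    hypertrophic lagoon so the whole pipeline is testable without imagery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    tibble,
    jsonlite,
    yaml
Suggests:
    tiff,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
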