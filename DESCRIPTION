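Package: PhotoCascade
Title: Seasonal Photosynthetic Energy-Conversion Efficiency from Canopy
    Chlorophyll Fluorescence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Converts long-term canopy chlorophyll-fluorescence (Fq'/Fm')
    and spectral scans of crop genotypes into photosynthetic
    energy-conversion efficiencies and biomass estimates. Provides typed
    CSV schemas for fluorescence, weather, biomass and gas-exchange
    records; spectral preprocessing (even-nm binning, gray-reference
    reflectance correction, PRI/NPQI/NDVI indices, light-adapted and
    grouped IQR filtering, per-minute averaging); fixed-effects genotype
    x environment models yielding adjusted means and genotype-specific
    Fq'/Fm'-vs-PPFR response slopes; a ridge-penalized hourly seasonal
    prediction model with regularized iterative-PCA imputation of
    missing spectral covariates and day-blocked cross-validation; the
    electron-transport/energy cascade (ETR, seasonal ET, epsilon_e,
    epsilon_t, epsilon_c); and a seeded synthetic-season generator with
    known ground truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    emmeans,
    MASS,
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
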