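# PhotoCascade

Seasonal photosynthetic energy-conversion efficiency from canopy
chlorophyll fluorescence.

## The problem

Crop biomass production can be written as an energy cascade: incident
photosynthetically active radiation (PPFR, µmol photons m⁻² s⁻¹) is
intercepted by the canopy with efficiency ε\_i, converted to photochemical
energy with efficiency ε\_e, and transduced into biomass energy with
efficiency ε\_t, so that over a growing season

    biomass energy = Σ (PPFR · 3600 s) · 0.219 J µmol⁻¹ · ε_i · ε_e · ε_t

and ε\_c = ε\_e · ε\_t is the classical radiation-use efficiency of
intercepted light. ε\_e and ε\_t are normally hidden inside ε\_c;
separating them requires a measurement of instantaneous photochemistry.
The operating efficiency of photosystem II, F\_q′/F\_m′, measured
repeatedly at canopy level by an automated fluorometer under incident
sunlight, provides exactly that: the electron transport rate is

    ETR = F_q′/F_m′ · PPFR · 0.5 · ε_i        (µmol electrons m⁻² s⁻¹)

and the PPFR-weighted seasonal mean of F\_q′/F\_m′ between germination
(21 days after sowing) and senescence (21 days before harvest) is ε\_e.
Because F\_q′/F\_m′ declines roughly linearly with light, each genotype's
fitted slope against PPFR (Response\_G:PPFR, from a fixed-effects
genotype × environment model with humidity, PPFR, PRI and pNDVI
covariates) is a compact, biomass-predictive summary of its
photoprotective behaviour.

The package is aimed at crop phenomics groups running long-term
fluorescence + spectral monitoring who want to turn those scans into
per-genotype ε\_e, ε\_t, ε\_c and biomass estimates, and at method
developers who need a fully seeded synthetic testbed for such pipelines.

## What is in the package

* **IO schemas** — typed CSV readers/writers for fluorescence (`lift`),
  per-minute weather, biomass and gas-exchange tables, plus the
  minute × condition weather join (`readDataset()`, `alignEnvironment()`).
* **Preprocessing** — even-nm spectral binning, gray-reference
  reflectance correction via a PPFR lookup table, absorption and
  PRI/NPQI/NDVI indices (raw "p" variants included), light-adapted
  selection (PPFR > 100), grouped 2.5 × IQR outlier removal, per-minute
  averaging (`preprocessRecords()` and friends).
* **G × E response models** — OLS fits of the maize-style
  (genotype-level) and soybean-style (plot-level) fixed-effects models;
  response slopes and adjusted means with delta-method standard errors;
  Pearson correlation with biomass (`fitGxE()`, `responseSlopes()`,
  `adjustedMeans()`, `correlateWithBiomass()`).
* **Seasonal prediction** — hourly season grid, regularized iterative-PCA
  imputation of missing spectral covariates, ridge-penalized hourly
  F\_q′/F\_m′ model with internal cross-validation for the penalty, and
  day-blocked 2/3 : 1/3 cross-validation (`buildSeasonGrid()`,
  `imputeSpectral()`, `fitRidge()`, `predictSeason()`,
  `crossvalidateByDay()`).
* **Efficiency cascade** — ETR, seasonal ET, ε\_e, biomass-to-energy
  accounting (18 MJ kg⁻¹, root fractions 9 %/17 %, field-maize stover
  39 %), ε\_t, ε\_c and genotype-adjusted means (`etr()`, `seasonalET()`,
  `epsilonE()`, `epsilonT()`, `epsilonC()`, `efficiencyFromFit()`).
* **Synthetic seasons** — a seeded generator for whole experiments
  (minute weather, sparse scan campaigns, spectra, biomass) with known
  ground truth for recovery testing (`synthConfig()`,
  `simulateExperiment()`).
* **Orchestration** — `runPipeline()` chains the stages and writes
  provenance-stamped CSVs; `matchEtrAssimilation()` pairs predicted ETR
  with gas-exchange CO₂ assimilation by half-hour and plot.

## Worked example

```r
library(PhotoCascade)

cfg <- synthConfig(seed = 7, nGenotypes = 4)   # 120-day season, 30 scan days
out <- runPipeline(config = cfg, modelKind = "maize", seed = 7)

out$slopes
#>   genotype         slope           se
#> 1      G01 -0.0001553591 6.960587e-06
#> 2      G02 -0.0001795313 6.894596e-06
#> 3      G03 -0.0001831536 6.852107e-06
#> 4      G04 -0.0002403492 6.828831e-06

out$correlation$r
#> [1] 0.8798614

out$efficiencies
#>   genotype seasonal_et cumulative_ppfr epsilon_e    method  epsilon_t  epsilon_c
#> 1      G01   914942889      3283223948 0.6192713 predicted 0.04322185 0.02676605
#> 2      G02   884847489      3283223948 0.5989015 predicted 0.04426357 0.02650952
#> 3      G03   843544567      3283223948 0.5709460 predicted 0.04389997 0.02506451
#> 4      G04   775226604      3283223948 0.5247055 predicted 0.04628609 0.02428657
```

The slopes are each genotype's F\_q′/F\_m′ change per unit PPFR (more
negative = stronger photoprotective down-regulation in high light); their
correlation with generated biomass is strongly positive because a
shallower decline means more electrons per intercepted photon. The
efficiency table gives the seasonal electron transport (µmol e⁻ m⁻²),
cumulative PPFR (µmol m⁻²), and the cascade ε\_e, ε\_t, ε\_c per
genotype — here recovering the generator's configured ε\_t ≈ 0.045 from
the generated biomass.

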