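---
title: "From canopy fluorescence scans to energy-conversion efficiencies"
author: "PhotoCascade authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From canopy fluorescence scans to energy-conversion efficiencies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PhotoCascade)
```

## The model

Biomass production is treated as an energy cascade. Over a growing
season, incident photosynthetically active radiation (PPFR, µmol photons
m⁻² s⁻¹) is intercepted with efficiency $\varepsilon_i$, converted into
photochemical energy with efficiency $\varepsilon_e$, and transduced into
biomass energy with efficiency $\varepsilon_t$:

$$E_{\text{biomass}} \;=\; \sum_{\text{germination}}^{\text{senescence}}
 (\mathrm{PPFR}\cdot 3600\,\mathrm{s}) \cdot 0.219\,\mathrm{J\,µmol^{-1}}
 \cdot \varepsilon_i \cdot \varepsilon_e \cdot \varepsilon_t ,$$

with $\varepsilon_c = \varepsilon_e \varepsilon_t$ the familiar
radiation-use efficiency of intercepted light. The cascade is closed by
the operating efficiency of photosystem II, $F_q'/F_m'$, measured at
canopy level under incident sunlight: the electron transport rate is
$\mathrm{ETR} = F_q'/F_m' \cdot \mathrm{PPFR} \cdot 0.5 \cdot
\varepsilon_i$ (half the photon flux is apportioned to PSII), seasonal
electron transport is the 3600-s hourly sum of ETR, and

$$\varepsilon_e = \frac{\sum F_q'/F_m' \cdot \mathrm{PPFR}}
                       {\sum \mathrm{PPFR}}$$

is the PPFR-weighted seasonal mean of $F_q'/F_m'$ —
$\varepsilon_i$ cancels, a property the test suite asserts.
$\varepsilon_t$ is obtained by inverting the cascade with measured
biomass, after scaling the measured plant part up to total biomass
(root fraction 9 % for maize and 17 % for soybean; field-maize grain
additionally carries a 39 % stover fraction) and converting dry mass to
energy at 18 MJ kg⁻¹. The seasonal window runs from germination (21 days
after sowing) to senescence (21 days before harvest).

### The G × E response model

$F_q'/F_m'$ reacts within minutes to light: it declines roughly linearly
with PPFR as photoprotective quenching engages, with genotype-specific
steepness. On minute-averaged records the package fits, by ordinary
least squares, a fixed-effects model with experiment, genotype and
replicate-nested-in-experiment × treatment factors, humidity, PPFR, PRI
and pNDVI covariates, a PPFR × PRI interaction, and genotype
interactions with PPFR, PRI and PPFR × PRI. Two variants are supported:
interactions at genotype level (suited to sparser data, "maize" style)
or at plot level ("soybean" style, absorbing spatial container effects).
The genotype response slope — the derivative of expected $F_q'/F_m'$ in
PPFR with the other covariates at their grand means — is extracted as a
prediction difference over a unit PPFR step, with delta-method standard
errors from the coefficient covariance; adjusted genotype means are
model predictions averaged with equal weight per experiment and, within
an experiment, per observed replicate cell. Because the slope multiplies
PPFR in the weighted mean above, $\varepsilon_e - \text{intercept}$ is
exactly proportional to the slope for a fixed PPFR series, which is why
the slope alone is a biomass-predictive trait.

### The hourly seasonal model

For hours without measurements the package fits a ridge-penalized linear
model on hourly averages inside the 100–2000 µmol m⁻² s⁻¹ window:
intercept (unpenalized, the training mean) plus equally L2-penalized
one-hot blocks for experiment and genotype, a seasonal/optical block
(month, hour, irradiance at 680 nm, absorption, and mean reflectance
when available), an environmental block (PRI, pNDVI, NPQI, DAS,
humidity, temperature, PPFR, √PPFR), and genotype × environmental
interactions. This single-penalty ridge is the standard deterministic
counterpart of treating those blocks as independent random effects with
a common variance ratio; per-block penalties are deliberately out of
scope. All columns are standardized to mean 0, SD 1 on the training
records; the penalty is chosen by seeded 10-fold record-level
cross-validation over a 100-point log-spaced grid ($10^{-5}$–$10^{5}$),
and the solution path is computed in closed form from one SVD.
Predictions are clipped to [0, 1].

Missing spectral covariates on unmeasured hours are completed per
genotype by regularized iterative PCA on the numeric covariate block:
missing cells start at column means, the standardized matrix is
reconstructed from its first six principal components with singular
values shrunken by the mean trailing eigenvalue (which pulls imputed
cells toward the column means), only missing cells are re-imputed, and
iteration stops when the relative squared change falls below $10^{-6}$
(cap 1000 iterations, with a warning on non-convergence). Observed cells
are never modified. The component count (6) and the tolerances are
package choices; the algorithm family is fixed by the method.

### Day-blocked cross-validation

Prediction accuracy is assessed by splitting the measuring *days* —
never records — into ⌊2/3⌋ training and the remaining validation days,
fitting entirely on training days (standardization, penalty selection
and the imputation all see only training-day fluorescence), and
correlating predicted with measured hourly $F_q'/F_m'$ on the held-out
days, replicates averaged. The run is done twice: once with the
validation days' spectral covariates observed (as if an independent
spectral sensor were available) and once with them removed and imputed.
On the default synthetic regime the observed-spectra run is the more
accurate one, because the day-level spectral information cannot be
reconstructed from weather and calendar alone.

## The synthetic-data generator

The generator emulates a container/glasshouse soybean campaign and is
the package's study condition, not a tuning dial. Defaults: a 120-day
season; 8 genotypes × 2 replicates; scans on 30 days spread over DAS
25–95, hourly 09:00–16:00, one scan minute per genotype × replicate;
minute-resolution weather with a half-sinusoid 14-h daylight PPFR
peaking at 1600 µmol m⁻² s⁻¹ scaled by a day-level beta cloud multiplier
(0.25–1, Beta(3, 1)); temperature 12–28 °C co-varying with light
(90-min lag) and humidity 45–95 % anti-varying on its own diurnal phase
with day-level offsets, so neither is an exact function of PPFR.
$F_q'/F_m'$ follows $a_g + b_g\,\mathrm{PPFR} + c_g\,\mathrm{PRI}$ plus
N(0, 0.03) noise, clipped to [0, 1] (the clipped fraction is reported
and negligible at the defaults): intercepts $a_g \sim$ N(0.78, 0.02),
slopes $b_g \sim$ N(−1.8 × 10⁻⁴, 4 × 10⁻⁵) per µmol m⁻² s⁻¹, PRI
coefficients $c_g \sim$ N(0.15, 0.05). PRI drifts linearly over the
season (−8 × 10⁻⁴ per day from 0.02) with a light-linked term
(−2 × 10⁻⁵ per µmol m⁻² s⁻¹), a day-level random component
(SD 0.03) representing canopy-structure variation that the spectra track
but weather cannot predict, and N(0, 0.01) measurement noise. Only
light-adapted records (PPFR > 100) are emitted. Biomass is generated by
running the cascade forwards from the noiseless genotype response
(true $\varepsilon_e$) and a configured true $\varepsilon_t$ (default
0.045 for every genotype), with mean-one lognormal replicate noise
(SD 0.05); a `curvature` switch substitutes a mildly saturating PPFR
response as a misspecification stressor.

What the generator does *not* emulate — and what passing tests therefore
do not establish about real data — includes vertical canopy structure
and within-canopy light gradients (the cascade here is a one-layer
approximation), instrument distance effects on the fluorescence yield,
radiative-transfer realism in the spectra, spatial field trends, and
weather regimes beyond smooth diurnal cycles with day-level cloud. The
recovery results say the estimators are correct under the stated model,
not that the model captures every field phenomenon.

## Numerical and design choices

* **Quartiles** for the 2.5 × IQR filter use linear interpolation
  between order statistics (the common "type 7" rule); groups smaller
  than 4 pass through and are logged. Filtering precedes minute
  averaging.
* **Band extraction and binning** snap to the nearest even nanometre
  with ties broken toward the lower even number; lookup-table selection
  snaps to the nearest PPFR key, ties toward the lower key, and field
  tables scale one reference spectrum linearly over a 200–1500 grid
  (snapped, not interpolated — the construction leaves either choice
  defensible, and snapping is the simpler contract to test).
* **Covariates are centered** before interaction columns are built;
  slopes are algebraically unchanged (asserted by an invariance test)
  while collinearity drops.
* **Aliased design columns** are removed deterministically
  left-to-right in the stated term order during the QR factorization;
  removed coefficients act as zeros, which keeps every estimable
  prediction combination exact.
* **Units** cross one boundary only: cumulative PPFR stays in µmol
  photons m⁻² everywhere and becomes joules (× 0.219) only inside the
  $\varepsilon_t$ inversion, so the conversion cannot be applied twice.
* **Two efficiency paths** are provided. The *predicted* path evaluates
  the fitted G × E model per genotype at each hourly PPFR (other
  covariates at grand means) over all daylight hours; on data generated
  from the model's own mean structure it inverts the generator exactly,
  which is the basis of the round-trip tests. The *extrapolated* path
  follows the field convention: a common low-light intercept (mean
  $F_q'/F_m'$ at PPFR < 105) plus the genotype slope. The low-light
  mean is itself evaluated at PPFR ≈ 100, not 0, so this path carries a
  small intercept bias by construction and is the robust, not the
  exact, estimator; with only light-adapted records available the
  intercept band (100, 105) may be empty, in which case the pipeline
  reports the path as unavailable rather than guessing.
* **Rounding** of report tables follows the published convention
  (3 decimals for efficiencies, 2 for correlations, R's round-half-even)
  while machine-precision values are kept in all returned objects.
* **Problem sizes in the test suite** (two-genotype noiseless seasons,
  100–200 replications of the default regime, 18-day cross-validation
  campaigns, 20-seed baseline comparisons) are the package's chosen
  compromise between statistical resolution and a test suite that runs
  in minutes; every size is stated in the test that uses it.

## Known limitations

The ridge model's random-effect reading assumes one shared penalty; data
with very different block scales would motivate per-block penalties.
The imputation assumes the covariate block is approximately low-rank;
purely idiosyncratic spectral variation is pulled toward column means.
Slope-based biomass prediction presumes a common low-light intercept
across genotypes within a crop — genuine intercept variation shows up as
$\varepsilon_e$ error in the extrapolated path. The ETR/assimilation
comparison pairs half-hour × plot means and is only as good as the
clock synchronisation of the two instruments. Finally, adjusted means
for genotypes confined to a single experiment rest on the additivity of
experiment effects and are flagged accordingly.
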