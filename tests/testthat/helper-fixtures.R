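# Shared fixtures: small seeded configs and toy spectra, built in code.

# Compact noisy default-style config (shorter season, fewer days) for
# tests that only need realistic structure, not the full default regime.
smallConfig <- function(seed = 1, ...) {
  args <- list(
    seed = seed,
    sowing = as.Date("2017-05-01"),
    harvest = as.Date("2017-07-29"),  # 90-day season
    nGenotypes = 4L, nReplicates = 2L,
    measurementDays = as.Date("2017-05-01") +
      unique(round(seq(25, 80, length.out = 12))),
    runHours = 10:15)
  override <- list(...)
  args[names(override)] <- override
  do.call(synthConfig, args)
}

# Noiseless, equal-intercept, PRI-free config: the exact-inversion regime.
noiselessConfig <- function(seed = 1, ...) {
  smallConfig(seed = seed, interceptSD = 0, priCoefMean = 0, priCoefSD = 0,
              priNoiseSD = 0, fqfmNoiseSD = 0, indexNoiseSD = 0,
              biomassNoiseSD = 0, ...)
}

# Simulate + align + preprocess in one go.
preprocessedExperiment <- function(config) {
  sim <- simulateExperiment(config)
  sim$pre <- preprocessRecords(alignEnvironment(sim$records, sim$weather))
  sim
}

# A smooth toy plant spectrum on the even-nm grid 400..800.
toySpectrum <- function(scale = 1) {
  wl <- seq(400L, 800L, by = 2L)
  data.frame(wavelength = wl,
             signal = scale * (1000 + 500 * sin((wl - 400) / 60)))
}

flatSpectrum <- function(value = 1000) {
  wl <- seq(400L, 800L, by = 2L)
  data.frame(wavelength = wl, signal = rep(value, length(wl)))
}

# Independent textbook type-7 quartile: linear interpolation between
# order statistics, written out by hand (oracle for iqrFilter).
oracleQuartile <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p + 1
  lo <- floor(h)
  x[lo] + (h - lo) * (x[min(lo + 1, length(x))] - x[lo])
}

# A tiny two-genotype season-grid-like frame with p w-covariates, for
# exercising the ridge solver against closed forms.
toyRidgeGrid <- function(n = 20, p = 5, seed = 4, noise = 0.1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  y <- drop(X %*% rnorm(p)) + rnorm(n, 0, noise)
  grid <- data.frame(X)
  names(grid) <- c("pri", "pndvi", "npqi", "das", "humidity")[seq_len(p)]
  grid$fqfm <- y
  grid$in_window <- TRUE
  grid$genotype <- rep(c("G01", "G02"), length.out = n)
  grid$timestamp <- as.POSIXct("2017-06-01", tz = "UTC") +
    seq_len(n) * 86400
  attr(grid, "vCols") <- character(0)
  attr(grid, "wCols") <- names(grid)[seq_len(p)]
  grid
}

# The ridge model's standardized design, rebuilt outside fitRidge.
standardizedDesign <- function(grid, fit) {
  X <- PhotoCascade:::.ridgeDesign(grid, fit@meta)[, names(fit@beta)]
  sweep(sweep(X, 2, fit@center), 2, fit@scale, "/")
}

table1Path <- function() {
  system.file("extdata", "table1_efficiencies.csv",
              package = "PhotoCascade")
}
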